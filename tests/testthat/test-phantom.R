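test_that("phantom generation is a pure function of spec and seed", {
  sp <- phantom_spec(grid_shape = c(16, 16, 6), cord_radius = 3,
                     noise_sd = c(PD = 0.02, R1 = 0.02, R2star = 0.5),
                     seed = 9)
  a <- make_cord_phantom(sp)
  b <- make_cord_phantom(sp)
  expect_identical(a$maps$PD, b$maps$PD)
  expect_identical(a$maps$R1, b$maps$R1)
  expect_identical(a$maps$R2star, b$maps$R2star)
  c <- make_cord_phantom(phantom_spec(grid_shape = c(16, 16, 6),
                                      cord_radius = 3,
                                      noise_sd = c(PD = 0.02, R1 = 0.02,
                                                   R2star = 0.5),
                                      seed = 10))
  expect_false(identical(a$maps$PD, c$maps$PD))
})

test_that("partial-volume fractions integrate to the analytic cylinder area", {
  k <- 5L
  ph <- small_phantom(4, seed = 1, k = k)
  # per-slice sum of cord fractions x in-plane voxel area vs pi r^2
  for (z in seq_len(dim(ph$cord_fraction)[3])) {
    area <- sum(ph$cord_fraction[, , z])
    expect_lt(abs(area - pi * 16) / (pi * 16), (1 / k)^2)
  }
  expect_equal(ph$ground_truth$csa_mm2, rep(pi * 16, 9))
})

test_that("tilted cylinders carry the elliptical cut area as ground truth", {
  ph <- small_phantom(4, tilt = 30, seed = 2, shape = c(40, 24, 30))
  expect_equal(unique(ph$ground_truth$cut_area_mm2), pi * 16 / cos(pi / 6))
  expect_equal(unique(ph$ground_truth$csa_mm2), pi * 16)
  # rasterized cut area agrees with the analytic ellipse on interior slices
  interior <- 8:23
  cut <- vapply(interior, function(z) sum(ph$cord_fraction[, , z]), 0)
  expect_lt(max(abs(cut - pi * 16 / cos(pi / 6))) / (pi * 16 / cos(pi / 6)),
            0.02)
})

test_that("degenerate phantom specs are rejected or flagged", {
  expect_error(phantom_spec(cord_radius = 0), "positive")
  expect_error(phantom_spec(cord_radius = -2), "positive")
  expect_warning(phantom_spec(cord_radius = 0.4), "smaller than one")
  expect_error(phantom_spec(tilt_deg = 90), "tilt")
  expect_error(phantom_spec(noise_sd = c(PD = -1, R1 = 0, R2star = 0)), ">= 0")
})

test_that("map perturbation is seeded, unbiased and identity at zero SD", {
  ph <- small_phantom(3, seed = 4, shape = c(14, 14, 6))
  expect_identical(perturb_maps(ph$maps, c(PD = 0, R1 = 0, R2star = 0), 1)$PD,
                   ph$maps$PD)
  p1 <- perturb_maps(ph$maps, c(PD = 0.05, R1 = 0.05, R2star = 1), seed = 5)
  p2 <- perturb_maps(ph$maps, c(PD = 0.05, R1 = 0.05, R2star = 1), seed = 5)
  expect_identical(p1$PD, p2$PD)
  p3 <- perturb_maps(ph$maps, c(PD = 0.05, R1 = 0.05, R2star = 1), seed = 6)
  expect_false(identical(p1$PD, p3$PD))
  # two independent perturbations share the underlying mean field
  n <- length(ph$maps$PD)
  se <- 0.05 * sqrt(2 / n)
  expect_lt(abs(mean(p1$PD) - mean(p3$PD)), 4 * se)
})

test_that("silenced cohort follows the fixed-effect polynomial exactly", {
  spec <- silent_cohort_spec(n_controls = 3, n_patients = 3,
                             modality_bias = c(reference = 0, synthetic = 0),
                             seed = 11)
  rec <- simulate_cohort(spec)
  wide <- tidyr::pivot_wider(rec, names_from = "modality",
                             values_from = "csa_mm2")
  expect_equal(wide$reference, wide$synthetic)
  pat <- rec[rec$group == "patient" & rec$level == "C2" &
               rec$modality == "reference", ]
  expected <- spec$patient_intercept + spec$patient_rate * pat$time_months +
    spec$patient_quad * pat$time_months^2
  expect_equal(pat$csa_mm2, expected)
})

test_that("cohort tables satisfy the record-schema invariants", {
  rec <- simulate_cohort(cohort_spec(n_controls = 5, n_patients = 5, seed = 3))
  expect_true(all(rec$csa_mm2 > 0))
  expect_identical(nrow(rec), 10L * 5L * 3L * 2L)
  expect_identical(anyDuplicated(rec[c("subject_id", "time_months", "level",
                                       "modality")]), 0L)
  expect_identical(rec,
                   simulate_cohort(cohort_spec(n_controls = 5, n_patients = 5,
                                               seed = 3)))
})

test_that("generated random effects match their specified moments", {
  spec <- cohort_spec(n_controls = 500, n_patients = 500,
                      timepoints = c(0, 12), levels = c("C1", "C2"),
                      level_offsets = c(C1 = 0, C2 = 0),
                      sd_intercept = 6, sd_slope = 0.08,
                      residual_sd = 0.0001, sd_level = 0, sd_quad = 0,
                      modality_noise = c(reference = 0, synthetic = 0),
                      age_time_coef = 0,
                      control_quad = 0, patient_quad = 0, seed = 21)
  rec <- simulate_cohort(spec)
  ref <- rec[rec$modality == "reference" & rec$level == "C1", ]
  wide <- tidyr::pivot_wider(ref, id_cols = c("subject_id", "group"),
                             names_from = "time_months",
                             values_from = "csa_mm2")
  # per-subject intercept and slope from the two timepoints
  slope <- (wide$`12` - wide$`0`) / 12
  inter <- wide$`0`
  n <- nrow(wide)
  expect_lt(abs(sd(inter) - 6), 4 * 6 / sqrt(2 * n))
  grp_rate <- ifelse(wide$group == "patient", spec$patient_rate,
                     spec$control_rate)
  expect_lt(abs(sd(slope - grp_rate) - 0.08), 4 * 0.08 / sqrt(2 * n))
})
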