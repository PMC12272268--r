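test_that("a noiseless cohort identifies every fixed effect exactly", {
  spec <- silent_cohort_spec(n_controls = 6, n_patients = 6,
                             modality_bias = c(reference = 0, synthetic = 0),
                             seed = 5)
  rec <- simulate_cohort(spec)
  fit <- fit_trajectory_model(rec, trajectory_spec("none", include_age = FALSE,
                                                   include_scanner = FALSE),
                              modality = "reference")
  td <- suppressWarnings(tidy(fit))
  est <- function(term) td$estimate[td$term == term]
  expect_equal(est("time_months"), spec$control_rate, tolerance = 1e-6)
  expect_equal(est("time_months:grouppatient"),
               spec$patient_rate - spec$control_rate, tolerance = 1e-6)
  expect_equal(est("I(time_months^2)"), spec$control_quad, tolerance = 1e-6)
  expect_equal(est("(Intercept)") , spec$control_intercept +
                 unname(spec$level_offsets["C1"]), tolerance = 1e-6)

  # marginal estimates reproduce the generative polynomial exactly
  m0 <- suppressWarnings(marginal_csa(fit, 0))
  expect_equal(m0$estimate[m0$term == "control"], spec$control_intercept,
               tolerance = 1e-6)
  expect_equal(m0$estimate[m0$term == "patient - control"],
               spec$patient_intercept - spec$control_intercept,
               tolerance = 1e-6)
  m24 <- suppressWarnings(marginal_csa(fit, 24))
  poly24 <- function(b0, b1, b2) b0 + b1 * 24 + b2 * 576
  expect_equal(m24$estimate[m24$term == "patient"],
               poly24(spec$patient_intercept, spec$patient_rate,
                      spec$patient_quad), tolerance = 1e-6)
})

test_that("every contrast equals the difference of its group estimates", {
  rec <- simulate_cohort(cohort_spec(n_controls = 10, n_patients = 10,
                                     seed = 31))
  fit <- fit_trajectory_model(rec, trajectory_spec("intercept_slope"),
                              modality = "reference")
  for (q in c("linear_rate", "quadratic")) {
    gc <- group_contrast(fit, q)
    expect_equal(gc$estimate[gc$term == "patient - control"],
                 gc$estimate[gc$term == "patient"] -
                   gc$estimate[gc$term == "control"],
                 tolerance = 1e-12)
  }
  m <- marginal_csa(fit, 12)
  expect_equal(m$estimate[m$term == "patient - control"],
               m$estimate[m$term == "patient"] -
                 m$estimate[m$term == "control"], tolerance = 1e-12)
})

test_that("adding a constant shifts intercepts but not rates", {
  rec <- simulate_cohort(cohort_spec(n_controls = 8, n_patients = 8,
                                     seed = 17))
  rec2 <- dplyr::mutate(rec, csa_mm2 = csa_mm2 + 10)
  sp <- trajectory_spec("intercept_slope")
  f1 <- fit_trajectory_model(rec, sp, modality = "synthetic")
  f2 <- fit_trajectory_model(rec2, sp, modality = "synthetic")
  r1 <- group_contrast(f1, "linear_rate")
  r2 <- group_contrast(f2, "linear_rate")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-3)
  m1 <- marginal_csa(f1, 0); m2 <- marginal_csa(f2, 0)
  expect_equal(m2$estimate[m2$term == "control"],
               m1$estimate[m1$term == "control"] + 10, tolerance = 1e-6)
})

test_that("the generative rate difference is recovered across replicates", {
  # scaled-down replicate study: 30 cohorts at the target cohort size
  diffs <- vapply(1:30, function(i) {
    rec <- simulate_cohort(cohort_spec(seed = 5000 + i))
    fit <- fit_trajectory_model(rec, trajectory_spec("intercept_slope"),
                                modality = "reference")
    gc <- group_contrast(fit, "linear_rate")
    gc$estimate[gc$term == "patient - control"]
  }, 0)
  expect_lt(abs(mean(diffs) - (-0.530)), 0.06)
})

test_that("identical groups yield a near-zero contrast", {
  spec <- cohort_spec(n_controls = 12, n_patients = 12,
                      patient_intercept = 66.15, patient_rate = 0.041,
                      patient_quad = -0.00136,
                      age_range_patients = c(17, 51), seed = 77)
  zs <- vapply(1:20, function(i) {
    spec$seed <- 7000 + i
    rec <- simulate_cohort(spec)
    fit <- fit_trajectory_model(rec, trajectory_spec("intercept_slope"),
                                modality = "reference")
    gc <- group_contrast(fit, "linear_rate")
    gc$estimate[gc$term == "patient - control"] /
      gc$se[gc$term == "patient - control"]
  }, 0)
  expect_gte(mean(abs(zs) < 3), 0.95)
})

test_that("singular random structures fall back down the documented ladder", {
  spec <- cohort_spec(n_controls = 8, n_patients = 8, sd_quad = 0,
                      sd_level = 0, seed = 13)
  rec <- simulate_cohort(spec)
  expect_message(
    fit <- fit_trajectory_model(rec, trajectory_spec("full"),
                                modality = "reference"),
    "reducing random structure")
  expect_true(fit$structure_used %in% c("slope_level", "intercept_slope",
                                        "none"))
  expect_true(fit$singular)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("records lacking design prerequisites are rejected", {
  rec <- simulate_cohort(cohort_spec(n_controls = 4, n_patients = 4,
                                     seed = 2))
  expect_error(fit_trajectory_model(rec[rec$group == "control", ]),
               "both groups")
  expect_error(fit_trajectory_model(rec[rec$time_months < 3, ]),
               "3 timepoints")
  expect_error(fit_trajectory_model(rec[rec$level == "C1", ]),
               "2 vertebral levels")
  fit <- fit_trajectory_model(rec, trajectory_spec("intercept_slope"),
                              modality = "reference")
  expect_error(group_contrast(fit, "marginal_at_t"), "`t`")
  expect_warning(marginal_csa(fit, 60), "outside the observed range")
})
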