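two_intensity_phantom <- function(...) {
  # cord inside a uniform surround (csf and background share one tissue);
  # subsample_k = 1 assigns whole voxels by center membership, so the
  # image carries exactly two intensities
  bgp <- list(PD = 0.3, R1 = 0.5, R2star = 20)
  make_cord_phantom(phantom_spec(
    grid_shape = c(20, 20, 9), cord_radius = 4, csf_thickness = 2.5,
    subsample_k = 1L,
    tissue_params = list(cord = list(PD = 0.7, R1 = 1.0, R2star = 30),
                         csf = bgp, background = bgp), ...))
}

test_that("thresholding a two-intensity phantom recovers the majority-voxel mask", {
  ph <- two_intensity_phantom(seed = 5, center_offset = c(0.3, -0.2))
  vol <- suppressWarnings(synthesize_volume(ph$maps,
                                            seq_params_ms(9, 960, 2420, 4, 10, 176)))
  m <- segment_cord(vol)
  expect_identical(m$mask, ph$cord_mask$mask)
})

test_that("segmentation rejects degenerate volumes", {
  expect_error(segment_cord(array(1, c(8, 8, 4))), "no cord")
  expect_error(segment_cord(array(NA_real_, c(8, 8, 4))), "no cord")
})

test_that("segmentation is invariant to global intensity scaling", {
  ph <- small_phantom(4, seed = 6, offset = c(0.2, 0.1))
  vol <- suppressWarnings(synthesize_volume(ph$maps,
                                            seq_params_ms(9, 960, 2420, 0, 10, 176)))
  m1 <- segment_cord(vol$data, voxel_spacing = vol$voxel_spacing)
  m10 <- segment_cord(vol$data * 10, voxel_spacing = vol$voxel_spacing)
  m001 <- segment_cord(vol$data * 0.01, voxel_spacing = vol$voxel_spacing)
  expect_identical(m1$mask, m10$mask)
  expect_identical(m1$mask, m001$mask)
})

test_that("noiseless cylinder CSA is recovered within the digitization bound", {
  ph <- small_phantom(4, seed = 3)
  vol <- suppressWarnings(synthesize_volume(ph$maps,
                                            seq_params_ms(14, 900, 1400, 0, 14, 176)))
  meas <- measure_csa(segment_cord(vol))
  # spec digitization bound: 2 * perimeter * voxel size
  expect_lt(abs(meas$overall_mm2 - pi * 16), 2 * 2 * pi * 4 * 1)
  # the realized error is far tighter (partial-volume bias documented)
  expect_lt(abs(meas$overall_mm2 - pi * 16), 3)
})

test_that("angle correction is the identity for an untilted cylinder", {
  ph <- small_phantom(4, seed = 3)
  meas <- measure_csa(ph$cord_mask)
  expect_equal(meas$slices$angle_deg, rep(0, 9))
  expect_identical(meas$slices$area_mm2, meas$slices$area_raw_mm2)
})

test_that("angle correction recovers the true area of a 30-degree cylinder", {
  ph <- small_phantom(4, tilt = 30, seed = 3, shape = c(48, 28, 40))
  meas <- measure_csa(ph$cord_mask)
  expect_lt(abs(meas$overall_mm2 - pi * 16) / (pi * 16), 0.05)
  expect_lt(abs(mean(meas$slices$area_raw_mm2) - pi * 16 / cos(pi / 6)) /
              (pi * 16 / cos(pi / 6)), 0.05)
  interior <- meas$slices$slice %in% 8:32
  expect_lt(max(abs(meas$slices$angle_deg[interior] - 30)), 3)
  # corrected area never exceeds raw area
  expect_true(all(meas$slices$area_mm2 <= meas$slices$area_raw_mm2 + 1e-12))
})

test_that("level means and the overall mean are plain arithmetic", {
  # two levels with per-slice areas {50, 50} and {52, 52}: rectangles with a
  # shared centroid so the centerline is straight
  mk_slice <- function(n_cells, nx = 20, ny = 20) {
    m <- matrix(FALSE, nx, ny)
    m[8:12, 6:15] <- TRUE                          # 5 x 10 = 50 cells
    if (n_cells == 52) {                           # add a centroid-neutral pair
      m[7, 10] <- TRUE
      m[13, 11] <- TRUE
    }
    m
  }
  mask <- array(FALSE, c(20, 20, 4))
  mask[, , 1] <- mk_slice(50); mask[, , 2] <- mk_slice(50)
  mask[, , 3] <- mk_slice(52); mask[, , 4] <- mk_slice(52)
  meas <- measure_csa(as_cord_mask(mask), levels = list(L1 = c(1, 2),
                                                        L2 = c(3, 4)))
  expect_equal(sort(meas$levels$csa_mm2), c(50, 52))
  expect_equal(meas$overall_mm2, 51)
})

test_that("measurement needs three nonempty slices and excludes empty ones", {
  m <- array(FALSE, c(10, 10, 5))
  m[4:6, 4:6, c(1, 3)] <- TRUE
  expect_error(measure_csa(as_cord_mask(m)), "3 nonempty")
  m[4:6, 4:6, 5] <- TRUE
  expect_message(meas <- measure_csa(as_cord_mask(m)), "empty slice")
  expect_identical(meas$slices$slice, c(1L, 3L, 5L))
})

test_that("level ranges must be disjoint and inside the volume", {
  ph <- small_phantom(4, seed = 3)
  expect_error(measure_csa(ph$cord_mask, levels = list(A = c(1, 5),
                                                       B = c(5, 9))),
               "disjoint")
  expect_error(measure_csa(ph$cord_mask, levels = list(A = c(1, 12))),
               "outside")
})

test_that("batch measurement yields one deterministic row per volume and level", {
  radii <- c(4.0, 4.1, 4.2)
  vols <- lapply(seq_along(radii), function(i) {
    ph <- small_phantom(radii[i], seed = 30 + i)
    suppressWarnings(synthesize_volume(ph$maps,
                                       seq_params_ms(9, 960, 2420, 4, 10, 176)))
  })
  names(vols) <- paste0("sub", 1:3)
  rows <- batch_csa(vols, nine_slice_levels)
  expect_identical(nrow(rows), 9L)
  expect_identical(unique(rows$volume_id), names(vols))
  for (i in seq_along(radii)) {
    got <- rows$csa_mm2[rows$volume_id == names(vols)[i]]
    expect_lt(max(abs(got - pi * radii[i]^2)), 5)
  }
  expect_identical(rows, batch_csa(vols, nine_slice_levels))
  expect_error(batch_csa(vols, list(C1 = c(1, 20))), "outside")
})

test_that("partial-volume refined areas track the analytic area more closely", {
  ph <- two_intensity_phantom(seed = 8, center_offset = c(0.31, 0.17))
  vol <- suppressWarnings(synthesize_volume(ph$maps,
                                            seq_params_ms(9, 960, 2420, 0, 10, 176)))
  m <- segment_cord(vol, pv_refine = TRUE)
  meas_c <- measure_csa(m)
  meas_r <- measure_csa(m, use_refined = TRUE)
  err_count <- abs(mean(meas_c$slices$area_raw_mm2) - pi * 16)
  err_ref <- abs(mean(meas_r$slices$area_raw_mm2) - pi * 16)
  expect_lt(err_ref, err_count + 0.5)
  expect_lt(err_ref / (pi * 16), 0.05)
})
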