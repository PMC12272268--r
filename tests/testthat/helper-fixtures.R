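# Shared fixtures, built in code at test time.

# A small noiseless phantom (20x20x9, 1 mm isotropic) with optional
# symmetry-breaking offset, as used by the calibration examples.
small_phantom <- function(r = 4, tilt = 0, seed = 11, offset = c(0, 0),
                          noise = c(PD = 0, R1 = 0, R2star = 0),
                          shape = c(20, 20, 9), k = 5L) {
  make_cord_phantom(phantom_spec(
    grid_shape = shape, cord_radius = r, csf_thickness = 2.5,
    tilt_deg = tilt, center_offset = offset, noise_sd = noise,
    subsample_k = k, seed = seed))
}

nine_slice_levels <- list(C1 = c(1, 3), C2 = c(4, 6), C3 = c(7, 9))

# Three symmetry-broken calibration phantoms with per-slice radius ramps.
calibration_phantoms <- function() {
  list(
    small_phantom(seq(3.80, 4.00, length.out = 9), tilt = 3, seed = 11,
                  offset = c(0.23, 0.41)),
    small_phantom(seq(4.25, 4.45, length.out = 9), tilt = 5, seed = 12,
                  offset = c(-0.37, 0.11)),
    small_phantom(seq(4.70, 4.90, length.out = 9), tilt = 2, seed = 13,
                  offset = c(0.05, -0.29)))
}

# Reference CSA for a list of phantoms under given parameters, through the
# standard synthesize -> segment -> measure path (median across levels).
reference_csa_for <- function(phantoms, params, levels = nine_slice_levels) {
  vapply(phantoms, function(p) {
    v <- suppressWarnings(synthesize_volume(p$maps, params))
    median(measure_csa(segment_cord(v), levels = levels)$levels$csa_mm2)
  }, 0)
}

# Independent fine-grid trapezoid quadrature of the JZS Bayes-factor
# integrand (10x the density integrate() needs), used as the oracle for
# jzs_bayes_factor().
jzs_quadrature_oracle <- function(x, y, r = sqrt(2) / 2, n_grid = 2e5) {
  n1 <- length(x); n2 <- length(y); nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / nu
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  N <- n1 * n2 / (n1 + n2)
  u <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  g <- u / (1 - u)
  f <- cordsynth:::jzs_integrand(g, tstat, N, nu, r) / (1 - u)^2
  num <- mean(f)
  num / (1 + tstat^2 / nu)^(-(nu + 1) / 2)
}

# Deterministic cohort with all random variation silenced.
silent_cohort_spec <- function(...) {
  cohort_spec(sd_intercept = 0, sd_slope = 0, sd_quad = 0, sd_level = 0,
              residual_sd = 0,
              modality_noise = c(reference = 0, synthetic = 0),
              age_time_coef = 0, ...)
}
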