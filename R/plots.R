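#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_line labs
#'   facet_wrap geom_col theme_minimal scale_colour_viridis_d geom_ribbon
NULL

#' Bland-Altman plot
#'
#' Mean-difference scatter with the bias and limits of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$summary
  p <- ggplot(object$data, aes(x = .data$mean, y = .data$diff))
  if (!all(is.na(object$data$group)))
    p <- p + geom_point(aes(colour = .data$group), alpha = 0.7)
  else p <- p + geom_point(alpha = 0.7)
  p +
    geom_hline(yintercept = s$bias, linewidth = 0.7) +
    geom_hline(yintercept = c(s$loa_lower, s$loa_upper), linetype = "dashed") +
    labs(x = "Mean of methods (mm²)",
         y = "Difference, comparison − reference (mm²)") +
    theme_minimal()
}

#' Per-slice CSA profile plot
#'
#' Raw and angle-corrected per-slice areas along the cord.
#'
#' @param object A [measure_csa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csa_measurement <- function(object, ...) {
  d <- tidyr::pivot_longer(object$slices,
                           c("area_raw_mm2", "area_mm2"),
                           names_to = "kind", values_to = "area")
  d$kind <- ifelse(d$kind == "area_mm2", "angle-corrected", "raw")
  ggplot(d, aes(x = .data$slice, y = .data$area, colour = .data$kind)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "Slice", y = "CSA (mm²)", colour = NULL) +
    theme_minimal()
}

#' Fitted group trajectories
#'
#' Model-implied group mean CSA over time (averaged across levels, age at
#' the cohort mean, reference scanner) with confidence ribbons, over the
#' observed time range.
#'
#' @param object A [fit_trajectory_model()] result.
#' @param n_points Number of evaluation timepoints.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_fit <- function(object, n_points = 25, ...) {
  ts <- seq(object$time_range[1], object$time_range[2], length.out = n_points)
  d <- purrr::map_dfr(ts, function(tt) {
    m <- marginal_csa(object, tt)
    m[m$term != "patient - control", ]
  })
  ggplot(d, aes(x = .data$t_months, y = .data$estimate,
                colour = .data$term, fill = .data$term)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                alpha = 0.15, colour = NA) +
    geom_line(linewidth = 0.8) +
    labs(x = "Time since enrollment (months)", y = "CSA (mm²)",
         colour = NULL, fill = NULL) +
    theme_minimal()
}

#' Sample-size surface plot
#'
#' Required per-group sample size against the treatment-effect fraction,
#' one line per baseline--follow-up correlation.
#'
#' @param object A [treatment_effect_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_size_table <- function(object, ...) {
  ggplot(object, aes(x = .data$effect_fraction, y = .data$n_per_group,
                     colour = factor(round(.data$rho, 3)),
                     group = factor(round(.data$rho, 3)))) +
    geom_line() + geom_point(size = 1) +
    labs(x = "Treatment-effect fraction", y = "n per group",
         colour = "baseline–follow-up r") +
    theme_minimal()
}
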