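#' Collapse CSA records to one method pair per subject and timepoint
#'
#' Averages CSA across vertebral levels within each (subject, timepoint,
#' modality) and spreads the two modalities into columns, so that one row is
#' one subject at one timepoint — the pairing unit of the agreement
#' analysis.
#'
#' @param records A CSA record tibble (see [simulate_cohort()]).
#' @param modalities Length-2 character: the reference and comparison
#'   modality, in that order.
#' @return A tibble with columns `subject_id`, `group`, `time_months` and
#'   one CSA column per modality.
#' @export
csa_pairs <- function(records, modalities = c("reference", "synthetic")) {
  stopifnot(length(modalities) == 2)
  keep <- records$modality %in% modalities
  if (!any(keep)) abort("No rows with the requested modalities.")
  agg <- dplyr::summarise(
    dplyr::group_by(records[keep, ], .data$subject_id, .data$group,
                    .data$time_months, .data$modality),
    csa_mm2 = mean(.data$csa_mm2), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "modality",
                             values_from = "csa_mm2")
  wide[complete.cases(wide[, modalities]), ]
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of the differences `b - a`), its limits of
#' agreement `bias +/- 1.96 * SD` (sample SD, expected to bracket ~95% of
#' individual differences), and their percentage counterparts relative to
#' the mean of the two method means. With a two-level `group` column the
#' analysis is additionally run per group, and the group biases are
#' compared with a default-prior Bayesian two-sample test
#' ([jzs_bayes_factor()]).
#'
#' @param data A data frame with one row per paired measurement.
#' @param a,b Columns (tidy-eval) holding the reference and comparison
#'   measurements.
#' @param group Optional column with exactly two groups.
#' @param loa_mult Limits-of-agreement multiplier (1.96 by default).
#' @return An object of class `bland_altman`: list with `summary` (one-row
#'   tibble), `by_group`, `bf` (a `jzs_bf` or `NULL`) and `data`
#'   (tibble of per-pair `mean` and `diff`).
#' @examples
#' df <- tibble::tibble(ref = c(50, 60, 70), syn = c(51, 62, 73))
#' bland_altman(df, ref, syn)$summary
#' @export
bland_altman <- function(data, a, b, group = NULL, loa_mult = 1.96) {
  a_v <- dplyr::pull(data, {{ a }})
  b_v <- dplyr::pull(data, {{ b }})
  g_q <- enquo(group)
  g_v <- if (rlang::quo_is_null(g_q)) NULL else dplyr::pull(data, !!g_q)
  ok <- is.finite(a_v) & is.finite(b_v)
  a_v <- a_v[ok]; b_v <- b_v[ok]
  if (!is.null(g_v)) g_v <- g_v[ok]
  if (length(a_v) < 2) abort("Bland-Altman needs at least 2 pairs.")
  ba_stats <- function(av, bv) {
    d <- bv - av
    bias <- mean(d)
    sdd <- sd(d)
    denom <- mean(c(mean(av), mean(bv)))
    tibble(n = length(d), mean_a = mean(av), mean_b = mean(bv),
           bias = bias, bias_pct = 100 * bias / denom,
           sd_diff = sdd,
           loa_lower = bias - loa_mult * sdd,
           loa_upper = bias + loa_mult * sdd,
           loa_lower_pct = 100 * (bias - loa_mult * sdd) / denom,
           loa_upper_pct = 100 * (bias + loa_mult * sdd) / denom)
  }
  summary <- ba_stats(a_v, b_v)
  by_group <- NULL; bf <- NULL
  if (!is.null(g_v)) {
    lv <- sort(unique(as.character(g_v)))
    by_group <- purrr::map_dfr(lv, function(l) {
      dplyr::mutate(ba_stats(a_v[g_v == l], b_v[g_v == l]), group = l,
                    .before = 1)
    })
    if (length(lv) == 2) {
      d <- b_v - a_v
      bf <- jzs_bayes_factor(d[g_v == lv[1]], d[g_v == lv[2]])
    }
  }
  structure(
    list(summary = summary, by_group = by_group, bf = bf,
         data = tibble(mean = (a_v + b_v) / 2, diff = b_v - a_v,
                       group = if (is.null(g_v)) NA_character_
                               else as.character(g_v))),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<bland_altman> n=%d  bias %.3f mm^2 (%.1f%%)  LoA [%.2f, %.2f] mm^2\n",
    s$n, s$bias, s$bias_pct, s$loa_lower, s$loa_upper))
  if (!is.null(x$bf))
    cat(sprintf("  group-bias comparison: BF10 = %.3g (%s)\n",
                x$bf$bf10, x$bf$label))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  if (is.null(x$by_group)) x$summary
  else dplyr::bind_rows(dplyr::mutate(x$summary, group = "all", .before = 1),
                        x$by_group)
}

#' @export
glance.bland_altman <- function(x, ...) {
  dplyr::mutate(x$summary,
                bf10 = if (is.null(x$bf)) NA_real_ else x$bf$bf10)
}

# JZS integrand over the effect-size prior scale g (before the g-prior).
jzs_integrand <- function(g, t, N, nu, r) {
  prior <- (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  (1 + N * g)^(-1 / 2) *
    (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) * prior
}

#' Default-prior (JZS) Bayes factor for a two-sample comparison
#'
#' Computes the Bayes factor BF10 of the two-sided alternative against the
#' null of equal means, placing a Cauchy prior with scale `prior_scale` on
#' the standardized effect size (Zellner-Siow / JZS default), by numerical
#' integration over the g-prior. On the Jeffreys scale, BF10 > 3 is read as
#' substantial evidence for a difference, BF10 < 1/3 as substantial
#' evidence for equivalence, and values between as inconclusive.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param prior_scale Cauchy prior scale r on the standardized effect
#'   (default `sqrt(2)/2`).
#' @return An object of class `jzs_bf`: list with `bf10`, `t`, `df`,
#'   `n` (per-group sizes), `prior_scale`, `label`.
#' @examples
#' set.seed(1)
#' jzs_bayes_factor(rnorm(30), rnorm(30))
#' @export
jzs_bayes_factor <- function(x, y, prior_scale = sqrt(2) / 2) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("Each sample needs at least 2 finite values.")
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / nu
  N <- n1 * n2 / (n1 + n2)
  degenerate <- sp2 == 0
  tstat <- if (degenerate) {
    if (mean(x) == mean(y)) 0 else Inf
  } else (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  if (degenerate && !is.finite(tstat))
    abort("Zero variance in both samples with different means: t is unbounded.")
  if (degenerate)
    warn("Zero variance in both samples; BF10 evaluated at the t = 0 limit.",
         class = "cordsynth_degenerate_bf")
  num <- integrate(jzs_integrand, 0, Inf, t = tstat, N = N, nu = nu,
                   r = prior_scale, rel.tol = 1e-10)$value
  den <- (1 + tstat^2 / nu)^(-(nu + 1) / 2)
  bf10 <- num / den
  label <- if (degenerate) "degenerate"
  else if (bf10 > 3) "evidence for difference"
  else if (bf10 < 1 / 3) "evidence for equivalence"
  else "inconclusive"
  structure(list(bf10 = bf10, t = tstat, df = nu, n = c(n1, n2),
                 prior_scale = prior_scale, label = label),
            class = "jzs_bf")
}

#' @export
print.jzs_bf <- function(x, ...) {
  cat(sprintf("<jzs_bf> BF10 = %.4g (t = %.3f, df = %d): %s\n",
              x$bf10, x$t, x$df, x$label))
  invisible(x)
}

#' Repeatability of CSA across repeated measurements
#'
#' For each subject, computes the sample SD of CSA across timepoints —
#' per vertebral level first and then averaged across levels (default), or
#' on the across-level mean series — and summarizes the cohort as the mean
#' and SD of the per-subject SDs. Intended for measurements expected to be
#' stable over the observation period (e.g. healthy controls). Subjects with
#' fewer than 2 timepoints are excluded with a message.
#'
#' @param records A CSA record tibble.
#' @param modality Which modality to assess.
#' @param per_level If `TRUE` (default), SD over time per level, then mean
#'   across levels; otherwise SD of the across-level mean series.
#' @return An object of class `repeatability`: list with `per_subject`
#'   (tibble: `subject_id`, `group`, `sd_mm2`, `n_timepoints`) and
#'   `summary` (tibble: `n_subjects`, `mean_sd_mm2`, `sd_sd_mm2`).
#' @export
repeatability_sd <- function(records, modality = "synthetic",
                             per_level = TRUE) {
  rec <- records[records$modality == modality, ]
  if (nrow(rec) == 0) abort("No rows with the requested modality.")
  nt <- dplyr::summarise(dplyr::group_by(rec, .data$subject_id),
                         n_timepoints = dplyr::n_distinct(.data$time_months),
                         .groups = "drop")
  drop <- nt$subject_id[nt$n_timepoints < 2]
  if (length(drop) > 0)
    inform(sprintf("Excluding %d subject(s) with a single timepoint.",
                   length(drop)))
  rec <- rec[!rec$subject_id %in% drop, ]
  if (nrow(rec) == 0) abort("No subject has repeated measurements.")
  per_subject <- if (per_level) {
    lv <- dplyr::summarise(
      dplyr::group_by(rec, .data$subject_id, .data$group, .data$level),
      sd_mm2 = sd(.data$csa_mm2), .groups = "drop")
    dplyr::summarise(dplyr::group_by(lv, .data$subject_id, .data$group),
                     sd_mm2 = mean(.data$sd_mm2), .groups = "drop")
  } else {
    mn <- dplyr::summarise(
      dplyr::group_by(rec, .data$subject_id, .data$group, .data$time_months),
      csa_mm2 = mean(.data$csa_mm2), .groups = "drop")
    dplyr::summarise(dplyr::group_by(mn, .data$subject_id, .data$group),
                     sd_mm2 = sd(.data$csa_mm2), .groups = "drop")
  }
  per_subject <- dplyr::left_join(per_subject, nt, by = "subject_id")
  structure(
    list(per_subject = per_subject,
         summary = tibble(n_subjects = nrow(per_subject),
                          mean_sd_mm2 = mean(per_subject$sd_mm2),
                          sd_sd_mm2 = sd(per_subject$sd_mm2))),
    class = "repeatability"
  )
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> %d subject(s): SD %.2f +/- %.2f mm^2\n",
              x$summary$n_subjects, x$summary$mean_sd_mm2,
              x$summary$sd_sd_mm2))
  invisible(x)
}

#' @export
tidy.repeatability <- function(x, ...) x$per_subject

#' @export
glance.repeatability <- function(x, ...) x$summary
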