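#' Specification of the longitudinal CSA trajectory model
#'
#' Fixed effects: vertebral level, time since enrollment (months, linear
#' and optionally quadratic to model deceleration) interacting with group,
#' an age-by-time interaction (age mean-centered across subjects), and
#' scanner. Random effects per subject follow `random_structure`:
#' `"full"` = intercept, time slope, quadratic time and level;
#' `"slope_level"` drops the quadratic; `"intercept_slope"` keeps intercept
#' and slope; `"none"` fits a fixed-effects-only linear model. With
#' `auto_reduce = TRUE` (default) a singular or non-converged fit is
#' automatically refit one step down this ladder, with a message.
#'
#' @param random_structure One of `"full"`, `"slope_level"`,
#'   `"intercept_slope"`, `"none"`.
#' @param include_quadratic Include quadratic time terms (fixed effects).
#' @param include_age Include the age-by-time covariate.
#' @param include_scanner Include scanner as a fixed effect (skipped
#'   automatically if the data carry no or a constant `scanner_id`).
#' @param REML Use restricted maximum likelihood (default) or ML.
#' @param df_method Degrees of freedom for tests: `"asymptotic"` (normal
#'   approximation, default) or `"satterthwaite"`.
#' @param auto_reduce Automatically reduce a singular random structure.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(random_structure = c("full", "slope_level",
                                                 "intercept_slope", "none"),
                            include_quadratic = TRUE,
                            include_age = TRUE,
                            include_scanner = TRUE,
                            REML = TRUE,
                            df_method = c("asymptotic", "satterthwaite"),
                            auto_reduce = TRUE) {
  structure(list(random_structure = match.arg(random_structure),
                 include_quadratic = include_quadratic,
                 include_age = include_age,
                 include_scanner = include_scanner,
                 REML = REML, df_method = match.arg(df_method),
                 auto_reduce = auto_reduce),
            class = "trajectory_spec")
}

re_term <- function(structure) {
  switch(structure,
         full = "(1 + time_months + I(time_months^2) + level | subject_id)",
         slope_level = "(1 + time_months + level | subject_id)",
         intercept_slope = "(1 + time_months | subject_id)",
         none = NULL)
}

reduce_ladder <- c(full = "slope_level", slope_level = "intercept_slope",
                   intercept_slope = "none")

#' Fit the longitudinal CSA trajectory model
#'
#' Fits the mixed-effects trajectory model of [trajectory_spec()] to a
#' long-format CSA record table (one modality at a time).
#'
#' @param records CSA record tibble; must contain `subject_id`, `group`,
#'   `time_months`, `level`, `csa_mm2` (plus `age_years`, `scanner_id` if
#'   the spec uses them).
#' @param spec A [trajectory_spec()].
#' @param modality Optional modality filter applied to `records`.
#' @return An object of class `trajectory_fit`: list with `model` (lmer or
#'   lm), `data`, `spec`, `formula`, `structure_used`, `mean_age`,
#'   `singular`.
#' @examples
#' rec <- simulate_cohort(cohort_spec(n_controls = 8, n_patients = 8, seed = 2))
#' fit <- fit_trajectory_model(rec, trajectory_spec("intercept_slope"),
#'                             modality = "reference")
#' tidy(fit)
#' @export
fit_trajectory_model <- function(records, spec = trajectory_spec(),
                                 modality = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  rec <- if (!is.null(modality)) records[records$modality == modality, ]
  else records
  if (nrow(rec) == 0) abort("No records to fit.")
  if (dplyr::n_distinct(rec$group) < 2) abort("Need both groups present.")
  if (dplyr::n_distinct(rec$time_months) < 3) abort("Need >= 3 timepoints.")
  if (dplyr::n_distinct(rec$level) < 2) abort("Need >= 2 vertebral levels.")
  dat <- dplyr::mutate(rec,
                       subject_id = factor(.data$subject_id),
                       group = factor(.data$group,
                                      levels = c("control", "patient")),
                       level = factor(.data$level))
  mean_age <- NA_real_
  use_age <- spec$include_age && "age_years" %in% names(dat)
  if (use_age) {
    subj_age <- dplyr::distinct(dat, .data$subject_id, .data$age_years)
    mean_age <- mean(subj_age$age_years)
    dat$age_c <- dat$age_years - mean_age
  }
  use_scanner <- spec$include_scanner && "scanner_id" %in% names(dat) &&
    dplyr::n_distinct(dat$scanner_id) > 1
  if (use_scanner) dat$scanner_id <- factor(dat$scanner_id)
  fixed <- c("level", "time_months * group",
             if (spec$include_quadratic) "I(time_months^2) * group",
             if (use_age) "age_c:time_months",
             if (use_scanner) "scanner_id")
  structure_used <- spec$random_structure
  singular <- FALSE
  repeat {
    re <- re_term(structure_used)
    fml <- stats::as.formula(
      paste("csa_mm2 ~", paste(c(fixed, re), collapse = " + ")))
    if (is.null(re)) {
      model <- lm(fml, data = dat)
      break
    }
    model <- tryCatch(
      lmerTest::lmer(fml, data = dat, REML = spec$REML,
                     control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e, warning = function(w) w)
    bad <- inherits(model, "condition") ||
      lme4::isSingular(model, tol = 1e-4)
    if (!bad) break
    singular <- TRUE
    if (!spec$auto_reduce || structure_used == "none") {
      if (inherits(model, "condition"))
        abort(paste0("Mixed-model fit failed: ", conditionMessage(model)))
      warn("Random-effect covariance is singular; keeping the requested structure.")
      break
    }
    structure_used <- reduce_ladder[[structure_used]]
    inform(sprintf("Singular random-effect fit; reducing random structure to \"%s\".",
                   structure_used))
  }
  structure(
    list(model = model, data = dat, spec = spec, formula = fml,
         structure_used = structure_used, mean_age = mean_age,
         singular = singular,
         time_range = range(dat$time_months)),
    class = "trajectory_fit"
  )
}

is_mixed <- function(fit) inherits(fit$model, "merMod")

emm_df_opts <- function(fit) {
  if (is_mixed(fit) && fit$spec$df_method == "asymptotic")
    list(lmer.df = "asymptotic")
  else list(lmer.df = "satterthwaite")
}

ref_at <- function(fit, t) {
  at <- list(time_months = t)
  if ("age_c" %in% names(fit$data)) at$age_c <- 0
  if ("scanner_id" %in% names(fit$data) &&
      is.factor(fit$data$scanner_id))
    at$scanner_id <- levels(fit$data$scanner_id)[1]
  at
}

#' Group estimates and patient-minus-control contrasts from a trajectory fit
#'
#' Reports, per group and as the patients - controls difference, one of:
#' the linear atrophy rate (the instantaneous slope at baseline,
#' mm^2/month), the quadratic (deceleration) term (mm^2/month^2), or the
#' marginal CSA at a chosen timepoint (mm^2, averaged across vertebral
#' levels, age at the cohort mean, reference scanner). Confidence intervals
#' and p-values come from the fixed-effect covariance; when several
#' contrasts are requested in one call they form the multiplicity family
#' and are adjusted by the multivariate-normal (Tukey-style) method.
#'
#' @param fit A [fit_trajectory_model()] result.
#' @param quantity `"linear_rate"`, `"quadratic"` or `"marginal_at_t"`.
#' @param t Timepoint(s) in months for `"marginal_at_t"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with rows for each group and each requested contrast:
#'   `quantity`, `term`, `estimate`, `se`, `conf.low`, `conf.high`,
#'   `p.value` (contrast rows only).
#' @export
group_contrast <- function(fit, quantity = c("linear_rate", "quadratic",
                                             "marginal_at_t"),
                           t = NULL, conf_level = 0.95) {
  quantity <- match.arg(quantity)
  if (quantity == "quadratic" && !fit$spec$include_quadratic)
    abort("The model was fit without quadratic time terms.")
  if (quantity == "marginal_at_t") {
    if (is.null(t)) abort("`t` (months) is required for marginal_at_t.")
    return(purrr::map_dfr(t, function(tt) marginal_csa(fit, tt)))
  }
  opts <- emm_df_opts(fit)
  if (quantity == "linear_rate") {
    emm <- do.call(emmeans::emtrends,
                   c(list(fit$model, ~group, var = "time_months",
                          at = ref_at(fit, 0)), opts))
  } else {
    # quadratic term per group via a linear transform of the fixed effects
    emm <- do.call(emmeans::emtrends,
                   c(list(fit$model, ~group, var = "time_months",
                          max.degree = 2, at = ref_at(fit, 0)), opts))
    emm <- emm[grep("quadratic", summary(emm)$degree)]
  }
  grp <- as_tibble(stats::confint(emm, level = conf_level))
  ctr <- as_tibble(summary(emmeans::contrast(emm, "revpairwise"),
                           infer = c(TRUE, TRUE), level = conf_level,
                           adjust = "mvt"))
  lc <- function(d) {
    nm <- names(d)
    names(d)[nm %in% c("asymp.LCL", "lower.CL")] <- "conf.low"
    names(d)[nm %in% c("asymp.UCL", "upper.CL")] <- "conf.high"
    names(d)[nm %in% c("time_months.trend", "emmean", "estimate")] <- "estimate"
    names(d)[nm == "SE"] <- "se"
    d
  }
  grp <- lc(grp); ctr <- lc(ctr)
  dplyr::bind_rows(
    tibble(quantity = quantity, term = as.character(grp$group),
           estimate = grp$estimate, se = grp$se,
           conf.low = grp$conf.low, conf.high = grp$conf.high,
           p.value = NA_real_),
    tibble(quantity = quantity, term = "patient - control",
           estimate = ctr$estimate, se = ctr$se,
           conf.low = ctr$conf.low, conf.high = ctr$conf.high,
           p.value = ctr$p.value))
}

#' Model-implied marginal CSA per group at a timepoint
#'
#' Marginal group means averaged over vertebral levels, with age at the
#' cohort mean and the reference scanner, evaluated at `t` months; includes
#' the patients - controls contrast. Extrapolation beyond the observed time
#' range is allowed with a warning.
#'
#' @inheritParams group_contrast
#' @param t Timepoint in months (scalar).
#' @return A tibble in the [group_contrast()] layout with an extra
#'   `t_months` column.
#' @export
marginal_csa <- function(fit, t, conf_level = 0.95) {
  stopifnot(inherits(fit, "trajectory_fit"), is.numeric(t), length(t) == 1)
  if (t < fit$time_range[1] || t > fit$time_range[2])
    warn(sprintf("t = %g months lies outside the observed range [%g, %g]; extrapolating.",
                 t, fit$time_range[1], fit$time_range[2]))
  opts <- emm_df_opts(fit)
  emm <- do.call(emmeans::emmeans,
                 c(list(fit$model, ~group, at = ref_at(fit, t)), opts))
  grp <- as_tibble(stats::confint(emm, level = conf_level))
  ctr <- as_tibble(summary(emmeans::contrast(emm, "revpairwise"),
                           infer = c(TRUE, TRUE), level = conf_level,
                           adjust = "mvt"))
  nmfix <- function(d) {
    nm <- names(d)
    names(d)[nm %in% c("asymp.LCL", "lower.CL")] <- "conf.low"
    names(d)[nm %in% c("asymp.UCL", "upper.CL")] <- "conf.high"
    names(d)[nm %in% c("emmean", "estimate")] <- "estimate"
    names(d)[nm == "SE"] <- "se"
    d
  }
  grp <- nmfix(grp); ctr <- nmfix(ctr)
  dplyr::bind_rows(
    tibble(quantity = "marginal_at_t", t_months = t,
           term = as.character(grp$group), estimate = grp$estimate,
           se = grp$se, conf.low = grp$conf.low, conf.high = grp$conf.high,
           p.value = NA_real_),
    tibble(quantity = "marginal_at_t", t_months = t,
           term = "patient - control", estimate = ctr$estimate, se = ctr$se,
           conf.low = ctr$conf.low, conf.high = ctr$conf.high,
           p.value = ctr$p.value))
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s random structure (%s), %d rows\n",
              x$structure_used,
              if (is_mixed(x)) "mixed model" else "fixed effects only",
              nrow(x$data)))
  print(x$formula)
  invisible(x)
}

#' @export
tidy.trajectory_fit <- function(x, ...) {
  cs <- coef(summary(x$model))
  out <- tibble(term = rownames(cs),
                estimate = unname(cs[, "Estimate"]),
                std.error = unname(cs[, "Std. Error"]))
  out$statistic <- unname(cs[, grep("value", colnames(cs))[1]])
  out$df <- if ("df" %in% colnames(cs)) unname(cs[, "df"]) else NA_real_
  pcol <- grep("^Pr", colnames(cs))
  out$p.value <- if (length(pcol) > 0) unname(cs[, pcol[1]]) else NA_real_
  out
}

#' @export
glance.trajectory_fit <- function(x, ...) {
  m <- x$model
  tibble(nobs = stats::nobs(m), sigma = stats::sigma(m),
         logLik = as.numeric(stats::logLik(m)),
         AIC = stats::AIC(m), BIC = stats::BIC(m),
         REML = if (is_mixed(x)) lme4::isREML(m) else FALSE,
         singular_reduced = x$singular,
         random_structure = x$structure_used)
}
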