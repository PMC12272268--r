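#' Reconstruction-parameter grid
#'
#' Full factorial grid over flip angle and timing parameters (milliseconds
#' at this boundary, matching protocol-table convention). The default ranges
#' span flip angle 6--14 degrees, TI 400--1000 ms, TR 1000--2500 ms,
#' TE 0--10 ms and ES 5--16 ms; default steps (2 degrees, 100 ms, 250 ms,
#' 2 ms, 1 ms) are round values chosen so the full default grid (17,640
#' cells) is exhaustively searchable on a single CPU in minutes.
#'
#' @param alpha_deg,TI_ms,TR_ms,TE_ms,ES_ms Numeric vectors of candidate
#'   values.
#' @param n_partitions Fixed partition count for every cell.
#' @return A tibble of grid cells with class `param_grid`.
#' @export
param_grid <- function(alpha_deg = seq(6, 14, by = 2),
                       TI_ms = seq(400, 1000, by = 100),
                       TR_ms = seq(1000, 2500, by = 250),
                       TE_ms = seq(0, 10, by = 2),
                       ES_ms = seq(5, 16, by = 1),
                       n_partitions = 176L) {
  for (v in list(alpha_deg, TI_ms, TR_ms, TE_ms, ES_ms))
    if (length(v) < 1 || anyDuplicated(v)) abort("Grid axes must be nonempty and duplicate-free.")
  g <- tidyr::expand_grid(alpha_deg = sort(alpha_deg), TI_ms = sort(TI_ms),
                          TR_ms = sort(TR_ms), TE_ms = sort(TE_ms),
                          ES_ms = sort(ES_ms),
                          n_partitions = as.integer(n_partitions))
  class(g) <- c("param_grid", class(g))
  g
}

row_to_params <- function(row) {
  seq_params_ms(row$alpha_deg, row$TI_ms, row$TR_ms, row$TE_ms, row$ES_ms,
                row$n_partitions)
}

#' Assemble a calibration set for parameter optimization
#'
#' @param maps_list List of [quant_maps()] objects, one per subject.
#' @param reference_csa Numeric vector of reference CSA values (mm^2), one
#'   per subject (e.g. measured on the subject's reference acquisition).
#' @param ids Optional subject identifiers.
#' @return A tibble with columns `subject`, `maps` (list), `reference_csa`.
#' @export
calibration_set <- function(maps_list, reference_csa, ids = NULL) {
  stopifnot(is.list(maps_list), length(maps_list) == length(reference_csa),
            length(maps_list) > 0)
  tibble(subject = ids %||% names(maps_list) %||%
           sprintf("sub%02d", seq_along(maps_list)),
         maps = unname(maps_list), reference_csa = as.numeric(reference_csa))
}

subject_csa <- function(volume_data, voxel_spacing, levels, morphometry,
                        aggregate) {
  m <- segment_cord(volume_data, method = morphometry$method %||% "midpoint",
                    threshold = morphometry$threshold,
                    voxel_spacing = voxel_spacing)
  meas <- measure_csa(m, levels = levels,
                      smooth_sigma = morphometry$smooth_sigma %||% 2)
  if (is.null(levels)) meas$overall_mm2
  else if (aggregate == "median") median(meas$levels$csa_mm2)
  else mean(meas$levels$csa_mm2)
}

#' Evaluate the CSA-difference objective for one parameter set
#'
#' For every calibration subject: synthesize the contrast volume with
#' `params`, segment, measure the per-level CSA, aggregate across levels
#' (median by default), and subtract the subject's reference CSA. Returns
#' the mean signed difference across subjects and the objective — by
#' default the absolute value of that mean. Subjects whose morphometry
#' fails are excluded with a message; if all fail, an error is raised.
#'
#' @param params A [seq_params()] object.
#' @param calibration A [calibration_set()].
#' @param levels Named list of slice ranges defining vertebral levels
#'   (optional; without it the overall slice mean is used).
#' @param morphometry List of morphometry settings (`method`, `threshold`,
#'   `smooth_sigma`).
#' @param aggregate Per-subject aggregation across levels: `"median"`
#'   (default) or `"mean"`.
#' @param objective Cohort objective: `"abs_mean"` (default, |mean signed
#'   difference|) or `"mean_abs"` (mean of |differences|).
#' @return A one-row tibble: `mean_diff_mm2`, `objective_mm2`, `n_subjects`.
#' @export
objective_eval <- function(params, calibration, levels = NULL,
                           morphometry = list(), aggregate = c("median", "mean"),
                           objective = c("abs_mean", "mean_abs")) {
  aggregate <- match.arg(aggregate)
  objective <- match.arg(objective)
  stopifnot(is_seq_params(params), nrow(calibration) > 0)
  diffs <- purrr::map_dbl(seq_len(nrow(calibration)), function(i) {
    tryCatch({
      vol <- suppressWarnings(synthesize_volume(calibration$maps[[i]], params))
      subject_csa(vol$data, vol$voxel_spacing, levels, morphometry,
                  aggregate) - calibration$reference_csa[i]
    }, error = function(e) {
      inform(sprintf("Subject %s excluded from objective: %s",
                     calibration$subject[i], conditionMessage(e)))
      NA_real_
    })
  })
  if (all(is.na(diffs))) abort("Morphometry failed for every calibration subject.")
  md <- mean(diffs, na.rm = TRUE)
  obj <- if (objective == "abs_mean") abs(md) else mean(abs(diffs), na.rm = TRUE)
  tibble(mean_diff_mm2 = md, objective_mm2 = obj,
         n_subjects = sum(!is.na(diffs)))
}

#' Exhaustive grid search for reconstruction parameters
#'
#' Evaluates the CSA-difference objective on every cell of a [param_grid()]
#' and returns the argmin, with ties broken by lexicographic parameter
#' order (flip angle, TI, TR, TE, ES ascending) and all tied cells
#' recorded. The steady-state factor Q does not depend on TE, so the search
#' reuses each (alpha, TI, TR, ES) synthesis across all TE values.
#'
#' @inheritParams objective_eval
#' @param grid A [param_grid()].
#' @param objective_fn Optional override for testing/composition: a
#'   function `(params_row) -> objective value` evaluated per cell instead
#'   of the synthesis pipeline.
#' @param progress Print progress every ~10% of cells.
#' @return An object of class `opt_result`: list with `best` (one-row
#'   tibble), `best_params` ([seq_params()]), `objective_mm2`, `trace`
#'   (tibble: one row per cell with `mean_diff_mm2`, `objective_mm2`),
#'   and `ties` (all cells attaining the minimum).
#' @export
grid_search <- function(grid, calibration = NULL, levels = NULL,
                        morphometry = list(), aggregate = c("median", "mean"),
                        objective = c("abs_mean", "mean_abs"),
                        objective_fn = NULL, progress = FALSE) {
  aggregate <- match.arg(aggregate)
  objective <- match.arg(objective)
  stopifnot(inherits(grid, "param_grid") || is.data.frame(grid))
  if (nrow(grid) == 0) abort("The parameter grid is empty.")
  cells <- dplyr::arrange(as_tibble(grid), .data$alpha_deg, .data$TI_ms,
                          .data$TR_ms, .data$TE_ms, .data$ES_ms)
  if (is.null(objective_fn)) {
    if (is.null(calibration) || nrow(calibration) == 0)
      abort("A nonempty calibration set is required.")
    trace <- grid_search_pipeline(cells, calibration, levels, morphometry,
                                  aggregate, objective, progress)
  } else {
    vals <- purrr::map_dbl(seq_len(nrow(cells)),
                           function(i) objective_fn(cells[i, ]))
    trace <- dplyr::mutate(cells, mean_diff_mm2 = NA_real_,
                           objective_mm2 = vals)
  }
  ok <- which(!is.na(trace$objective_mm2))
  if (length(ok) == 0) abort("Objective evaluation failed on every grid cell.")
  best_obj <- min(trace$objective_mm2[ok])
  tie_idx <- ok[trace$objective_mm2[ok] == best_obj]
  best_row <- trace[tie_idx[1], ]
  structure(
    list(best = best_row, best_params = row_to_params(best_row),
         objective_mm2 = best_obj, trace = trace, ties = trace[tie_idx, ]),
    class = "opt_result"
  )
}

grid_search_pipeline <- function(cells, calibration, levels, morphometry,
                                 aggregate, objective, progress) {
  nsub <- nrow(calibration)
  # per-subject constants
  pd <- lapply(calibration$maps, function(m) as.vector(m$PD))
  r1 <- lapply(calibration$maps, function(m) as.vector(m$R1))
  r2 <- lapply(calibration$maps, function(m) as.vector(m$R2star))
  vmask <- lapply(calibration$maps, function(m) as.vector(m$validity_mask))
  dims <- lapply(calibration$maps, function(m) dim(m$PD))
  spc <- lapply(calibration$maps, function(m) m$voxel_spacing)
  TEs <- sort(unique(cells$TE_ms))
  te_decay <- lapply(seq_len(nsub), function(i)
    lapply(setNames(TEs, paste0("te", TEs)),
           function(te) exp(-(te / 1000) * r2[[i]])))
  groups <- dplyr::distinct(cells, .data$alpha_deg, .data$TI_ms, .data$TR_ms,
                            .data$ES_ms, .data$n_partitions)
  trace <- dplyr::mutate(cells, mean_diff_mm2 = NA_real_,
                         objective_mm2 = NA_real_)
  key <- paste(cells$alpha_deg, cells$TI_ms, cells$TR_ms, cells$ES_ms,
               cells$n_partitions)
  done <- 0L
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    p0 <- seq_params_ms(g$alpha_deg, g$TI_ms, g$TR_ms, 0, g$ES_ms,
                        g$n_partitions)
    sina <- sin(g$alpha_deg * pi / 180)
    base <- lapply(seq_len(nsub), function(i) {
      ok <- vmask[[i]] & is.finite(r1[[i]]) & r1[[i]] >= 0
      q <- q_components(p0, ifelse(ok, r1[[i]], 0))$Q
      list(val = sina * pd[[i]] * q, ok = ok)
    })
    rows <- which(key == paste(g$alpha_deg, g$TI_ms, g$TR_ms, g$ES_ms,
                               g$n_partitions))
    for (ri in rows) {
      te_name <- paste0("te", cells$TE_ms[ri])
      diffs <- vapply(seq_len(nsub), function(i) {
        s <- base[[i]]$val * te_decay[[i]][[te_name]]
        s[!base[[i]]$ok] <- 0
        dim(s) <- dims[[i]]
        tryCatch(
          subject_csa(s, spc[[i]], levels, morphometry, aggregate) -
            calibration$reference_csa[i],
          error = function(e) NA_real_)
      }, 0)
      if (!all(is.na(diffs))) {
        md <- mean(diffs, na.rm = TRUE)
        trace$mean_diff_mm2[ri] <- md
        trace$objective_mm2[ri] <- if (objective == "abs_mean") abs(md)
          else mean(abs(diffs), na.rm = TRUE)
      }
      done <- done + 1L
      if (progress && done %% max(1L, nrow(cells) %/% 10L) == 0L)
        inform(sprintf("grid search: %d / %d cells", done, nrow(cells)))
    }
  }
  trace
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> %d cells searched, best objective %.4g mm^2 (%d tie(s))\n",
              nrow(x$trace), x$objective_mm2, nrow(x$ties)))
  print(x$best_params)
  invisible(x)
}

#' @export
tidy.opt_result <- function(x, ...) x$trace

#' @export
glance.opt_result <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$best, "alpha_deg", "TI_ms", "TR_ms", "TE_ms", "ES_ms"),
    objective_mm2 = x$objective_mm2, n_cells = nrow(x$trace),
    n_ties = nrow(x$ties))
}
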