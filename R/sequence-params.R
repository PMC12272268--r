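#' Sequence parameters for synthetic MPRAGE-contrast reconstruction
#'
#' Bundles the flip angle and timing parameters that define one synthetic
#' T1-weighted contrast. All times are stored in **seconds**; use
#' [seq_params_ms()] to enter the millisecond values conventionally printed
#' in protocol tables.
#'
#' @param flip_angle_deg Excitation flip angle alpha in degrees. Must lie in
#'   `[0, 90)`: the apparent relaxation time uses `log(cos(alpha))`, which is
#'   undefined at and beyond 90 degrees. A zero flip angle is admitted as the
#'   degenerate no-excitation limit (the signal is exactly 0).
#' @param TI Inversion time in seconds (> 0), measured from the inversion
#'   pulse to the central readout excitation.
#' @param TR Repetition time of the inversion cycle in seconds (> 0).
#' @param TE Echo time in seconds (>= 0).
#' @param ES Echo spacing between readout excitations in seconds (> 0).
#' @param n_partitions Number of partitions, i.e. excitations per inversion
#'   cycle (integer >= 1).
#'
#' @return An object of class `seq_params`: a named list with the fields
#'   above (times in seconds).
#' @seealso [derive_timing()], [compute_Q()], [synthesize_volume()]
#' @examples
#' p <- seq_params_ms(flip_angle_deg = 9, TI = 960, TR = 2420, TE = 4.18,
#'                    ES = 10, n_partitions = 176)
#' derive_timing(p)
#' @export
seq_params <- function(flip_angle_deg, TI, TR, TE = 0, ES, n_partitions) {
  stopifnot(is.numeric(flip_angle_deg), length(flip_angle_deg) == 1L)
  if (!is.finite(flip_angle_deg) || flip_angle_deg < 0 || flip_angle_deg >= 90)
    abort("`flip_angle_deg` must lie in [0, 90) degrees.")
  if (!is.finite(TI) || TI <= 0) abort("`TI` must be > 0 (seconds).")
  if (!is.finite(TR) || TR <= 0) abort("`TR` must be > 0 (seconds).")
  if (!is.finite(TE) || TE < 0) abort("`TE` must be >= 0 (seconds).")
  if (!is.finite(ES) || ES <= 0) abort("`ES` must be > 0 (seconds).")
  n_partitions <- as.integer(n_partitions)
  if (is.na(n_partitions) || n_partitions < 1L)
    abort("`n_partitions` must be a positive integer.")
  structure(
    list(flip_angle_deg = flip_angle_deg, TI = TI, TR = TR, TE = TE,
         ES = ES, n_partitions = n_partitions),
    class = "seq_params"
  )
}

#' @rdname seq_params
#' @description `seq_params_ms()` accepts `TI`, `TR`, `TE` and `ES` in
#'   milliseconds and converts them to seconds at the boundary.
#' @export
seq_params_ms <- function(flip_angle_deg, TI, TR, TE = 0, ES, n_partitions) {
  seq_params(flip_angle_deg, TI / 1000, TR / 1000, TE / 1000, ES / 1000,
             n_partitions)
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(
    "<seq_params> alpha=%g deg, TI=%g ms, TR=%g ms, TE=%g ms, ES=%g ms, n=%d\n",
    x$flip_angle_deg, x$TI * 1e3, x$TR * 1e3, x$TE * 1e3, x$ES * 1e3,
    x$n_partitions))
  invisible(x)
}

is_seq_params <- function(x) inherits(x, "seq_params")

#' Derive readout duration and delay time from sequence parameters
#'
#' Computes the readout-train duration `tau = n * ES` and the post-readout
#' delay `TD = TR - (TI - tau/2) - tau`. A negative `TD` (or an inversion
#' delay `TA = TI - tau/2 < 0`) means the timing could not be realized as an
#' actual acquisition; such parameter sets remain usable for reconstruction,
#' where no pulse-timing constraint applies, and are flagged `feasible =
#' FALSE`.
#'
#' @param params A [seq_params()] object.
#' @return A one-row tibble with columns `tau`, `TD`, `TA` (seconds) and
#'   `feasible` (`TD >= 0 & TA >= 0`).
#' @examples
#' derive_timing(seq_params_ms(14, TI = 900, TR = 1400, TE = 0, ES = 14,
#'                             n_partitions = 176))
#' @export
derive_timing <- function(params) {
  stopifnot(is_seq_params(params))
  tau <- params$n_partitions * params$ES
  TA <- params$TI - tau / 2
  TD <- params$TR - TA - tau
  tibble(tau = tau, TD = TD, TA = TA, feasible = TD >= 0 && TA >= 0)
}
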