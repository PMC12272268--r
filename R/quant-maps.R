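#' Container for co-registered quantitative maps
#'
#' Holds the three quantitative maps the signal model consumes — proton
#' density (PD, arbitrary units), longitudinal relaxation rate (R1, 1/s) and
#' effective transverse relaxation rate (R2*, 1/s) — as 3-D arrays on a
#' shared voxel grid, together with voxel spacing, a 4x4 affine and a
#' validity mask. Voxels that are non-finite or negative in any map are
#' marked invalid.
#'
#' @param PD,R1,R2star 3-D numeric arrays of identical shape.
#' @param voxel_spacing Numeric length-3, mm per axis (strictly positive).
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a
#'   diagonal affine built from `voxel_spacing`.
#' @param validity_mask Optional logical array; combined (AND) with the
#'   finiteness/non-negativity mask.
#' @return An object of class `quant_maps`.
#' @export
quant_maps <- function(PD, R1, R2star, voxel_spacing = c(1, 1, 1),
                       affine = NULL, validity_mask = NULL) {
  for (nm in c("PD", "R1", "R2star")) {
    v <- get(nm)
    if (!is.array(v) || length(dim(v)) != 3L)
      abort(sprintf("`%s` must be a 3-D array.", nm))
  }
  if (!identical(dim(PD), dim(R1)) || !identical(dim(PD), dim(R2star)))
    abort("PD, R1 and R2star must share an identical grid shape.")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    abort("`voxel_spacing` must be three strictly positive values (mm).")
  if (is.null(affine)) {
    affine <- diag(c(voxel_spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    abort("`affine` must be a 4x4 matrix.")
  finite_ok <- is.finite(PD) & is.finite(R1) & is.finite(R2star) &
    PD >= 0 & R1 >= 0 & R2star >= 0
  finite_ok[is.na(finite_ok)] <- FALSE
  mask <- finite_ok
  if (!is.null(validity_mask)) {
    if (!identical(dim(validity_mask), dim(PD)))
      abort("`validity_mask` must match the map grid shape.")
    mask <- mask & (validity_mask & !is.na(validity_mask))
  }
  structure(
    list(PD = PD, R1 = R1, R2star = R2star, voxel_spacing = voxel_spacing,
         affine = affine, validity_mask = mask),
    class = "quant_maps"
  )
}

is_quant_maps <- function(x) inherits(x, "quant_maps")

#' @export
print.quant_maps <- function(x, ...) {
  cat(sprintf("<quant_maps> %s voxels, spacing %s mm, %d invalid voxel(s)\n",
              paste(dim(x$PD), collapse = "x"),
              paste(signif(x$voxel_spacing, 3), collapse = "x"),
              sum(!x$validity_mask)))
  invisible(x)
}
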