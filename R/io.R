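nifti_from_array <- function(arr, voxel_spacing, affine = NULL) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_spacing
  if (!is.null(affine)) {
    RNifti::`sform<-`(img, structure(affine, code = 2L))
  } else img
}

array_from_nifti <- function(img) {
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr,
       voxel_spacing = RNifti::pixdim(img)[seq_len(3L)],
       affine = unname(unclass(RNifti::xform(img)))[seq_len(4L), seq_len(4L),
                                                    drop = FALSE])
}

#' Read quantitative maps from NIfTI files
#'
#' Reads PD, R1 and R2* volumes either from three separate NIfTI files or
#' from a single 4-D file whose fourth dimension stacks the maps in that
#' order. Geometry (voxel spacing and affine) must agree across files within
#' `tol`; NaN or negative voxels become invalid in the validity mask.
#'
#' @param paths Character vector: either length 3 (`PD`, `R1`, `R2star`) or
#'   length 1 (a 4-D file).
#' @param tol Tolerance for affine/spacing agreement between files.
#' @return A [quant_maps()] object.
#' @export
read_quantitative_maps <- function(paths, tol = 1e-4) {
  stopifnot(is.character(paths), length(paths) %in% c(1L, 3L))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    abort(paste0("Input file not found: ", paste(missing, collapse = ", ")))
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    arr <- as.array(img)
    if (length(dim(arr)) != 4L || dim(arr)[4L] != 3L)
      abort("A single input file must be 4-D with exactly 3 volumes (PD, R1, R2star).")
    spacing <- RNifti::pixdim(img)[seq_len(3L)]
    affine <- unname(unclass(RNifti::xform(img)))[1:4, 1:4, drop = FALSE]
    vols <- lapply(1:3, function(i) {
      v <- arr[, , , i]
      attributes(v) <- list(dim = dim(arr)[1:3])
      v
    })
  } else {
    parts <- lapply(paths, function(p) array_from_nifti(RNifti::readNifti(p)))
    shapes <- vapply(parts, function(p) paste(dim(p$data), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      abort(sprintf("Grid shape mismatch between input maps: %s.",
                    paste(shapes, collapse = " vs ")))
    for (i in 2:3) {
      if (max(abs(parts[[i]]$affine - parts[[1]]$affine)) > tol ||
          max(abs(parts[[i]]$voxel_spacing - parts[[1]]$voxel_spacing)) > tol)
        abort("Affine/spacing mismatch between input maps exceeds tolerance.")
    }
    spacing <- parts[[1]]$voxel_spacing
    affine <- parts[[1]]$affine
    vols <- lapply(parts, `[[`, "data")
  }
  quant_maps(vols[[1]], vols[[2]], vols[[3]], voxel_spacing = spacing,
             affine = affine)
}

#' Write quantitative maps to NIfTI files
#'
#' @param maps A [quant_maps()] object.
#' @param paths Character vector of length 3 (`PD`, `R1`, `R2star` files) or
#'   length 1 (one 4-D file).
#' @return `paths`, invisibly.
#' @export
write_quantitative_maps <- function(maps, paths) {
  stopifnot(is_quant_maps(maps), is.character(paths),
            length(paths) %in% c(1L, 3L))
  if (length(paths) == 1L) {
    arr <- array(c(maps$PD, maps$R1, maps$R2star), c(dim(maps$PD), 3L))
    RNifti::writeNifti(nifti_from_array(arr, c(maps$voxel_spacing, 1),
                                        maps$affine), paths)
  } else {
    vols <- list(maps$PD, maps$R1, maps$R2star)
    for (i in 1:3)
      RNifti::writeNifti(nifti_from_array(vols[[i]], maps$voxel_spacing,
                                          maps$affine), paths[i])
  }
  invisible(paths)
}

#' Read / write a contrast volume
#'
#' `write_volume()` writes a synthesized (or any) volume as NIfTI,
#' optionally min-max rescaled to 16-bit integers; `read_volume()` reads a
#' 3-D NIfTI into the same list structure `synthesize_volume()` returns
#' (without sequence parameters).
#'
#' @param volume A `synth_volume` or a 3-D array.
#' @param path Output/input NIfTI path (`.nii` or `.nii.gz`).
#' @param scale_int16 If `TRUE`, min-max scale intensities to 0..32767 and
#'   store as 16-bit integers.
#' @param voxel_spacing,affine Geometry, used when `volume` is a bare array.
#' @return `write_volume()`: `path`, invisibly. `read_volume()`: a
#'   `synth_volume`-shaped list.
#' @export
write_volume <- function(volume, path, scale_int16 = FALSE,
                         voxel_spacing = c(1, 1, 1), affine = NULL) {
  if (inherits(volume, "synth_volume")) {
    arr <- volume$data
    voxel_spacing <- volume$voxel_spacing
    affine <- volume$affine
  } else arr <- volume
  if (scale_int16) {
    rng <- range(arr, finite = TRUE)
    scl <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
    arr <- array(as.integer(round(scl * 32767)), dim(arr))
  }
  RNifti::writeNifti(nifti_from_array(arr, voxel_spacing, affine), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  p <- array_from_nifti(RNifti::readNifti(path))
  structure(
    list(data = p$data, voxel_spacing = p$voxel_spacing, affine = p$affine,
         validity_mask = is.finite(p$data), params = NULL),
    class = "synth_volume"
  )
}

#' Read / write long-format CSA record tables
#'
#' CSA records are long-format rows of (`subject_id`, `group`, `age_years`,
#' `scanner_id`, `time_months`, `level`, `modality`, `csa_mm2`) — the unit
#' of all downstream statistics. Files are plain UTF-8 comma-separated
#' values with a header row.
#'
#' @param records A data frame of CSA records.
#' @param path CSV path.
#' @return `read_csa_records()`: a tibble. `write_csa_records()`: `path`,
#'   invisibly.
#' @export
write_csa_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_csa_records
#' @export
read_csa_records <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("subject_id", "time_months", "level", "modality", "csa_mm2")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    abort(paste0("CSA record file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  df
}

#' Read vertebral level definitions from YAML
#'
#' Levels are user-supplied disjoint slice ranges, e.g.
#' `C1: [30, 40]`, meaning slices 30--40 (1-based, inclusive) belong to C1.
#'
#' @param path YAML file path.
#' @return Named list of integer ranges `c(from, to)`.
#' @export
read_level_definitions <- function(path) {
  defs <- yaml::read_yaml(path)
  lv <- lapply(defs, function(x) as.integer(x))
  bad <- names(lv)[vapply(lv, function(x) length(x) != 2L || x[1] > x[2], TRUE)]
  if (length(bad) > 0)
    abort(paste0("Malformed level range(s): ", paste(bad, collapse = ", ")))
  validate_level_ranges(lv)
  lv
}

validate_level_ranges <- function(levels) {
  if (length(levels) < 1L || is.null(names(levels)))
    abort("Level definitions must be a named list of slice ranges.")
  slices <- unlist(lapply(levels, function(r) seq(r[1], r[2])))
  if (anyDuplicated(slices))
    abort("Level slice ranges must be disjoint.")
  invisible(levels)
}
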