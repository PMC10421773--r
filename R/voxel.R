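#' Construct a 3-D T2 intensity grid
#'
#' Container for a block of T2-weighted signal intensities on an isotropic
#' voxel lattice, the raw material for threshold-based tissue quantification.
#' Intensities are abstract non-negative integers (scanner export units);
#' non-integer values are floored with a warning.
#'
#' @param values 3-D numeric array of non-negative intensities.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm
#'   (default 0.37, the acquisition used for molar imaging).
#' @return An object of class `intensity_grid`.
#' @export
intensity_grid <- function(values, voxel_size_mm = 0.37) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("`values` must be a non-empty 3-D array", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar", call. = FALSE)
  if (any(values != floor(values))) {
    warning("non-integer intensities floored to integers")
    values <- floor(values)
  }
  structure(list(values = values, voxel_size_mm = voxel_size_mm),
            class = "intensity_grid")
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat("<intensity_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", x$voxel_size_mm, " mm\n", sep = "")
  invisible(x)
}

#' Tissue volumes of one tooth
#'
#' The three segmented tissue volumes (ml) of one tooth of one participant:
#' hard tooth tissue (dentine + enamel + cementum, indistinguishable on the
#' T2 sequence), high-signal soft tissue (HSST, believed to be pulp) and
#' low-signal soft tissue (LSST, believed to be predentine).
#'
#' @param hard,hsst,lsst volumes in ml. All must be non-negative; an
#'   included tooth has all three strictly positive.
#' @return An object of class `tooth_volumes` (a named list).
#' @export
tooth_volumes <- function(hard, hsst, lsst) {
  v <- c(hard = hard, hsst = hsst, lsst = lsst)
  if (anyNA(v) || any(v < 0))
    stop("tissue volumes must be non-negative", call. = FALSE)
  structure(list(hard = hard, hsst = hsst, lsst = lsst,
                 total = hard + hsst + lsst),
            class = "tooth_volumes")
}

#' @export
print.tooth_volumes <- function(x, ...) {
  cat(sprintf("<tooth_volumes> hard %.4g  hsst %.4g  lsst %.4g  total %.4g ml\n",
              x$hard, x$hsst, x$lsst, x$total))
  invisible(x)
}

#' Classify voxel intensities into tissue labels
#'
#' Applies the printed T2 signal-intensity thresholds: 0--63 hard tooth
#' tissue, 64--100 low-signal soft tissue, >= 101 high-signal soft tissue
#' (all bounds inclusive).
#'
#' @param intensity vector of non-negative integer intensities.
#' @return factor with levels `hard`, `lsst`, `hsst`.
#' @examples
#' classify_voxel(c(0, 63, 64, 100, 101))
#' @export
classify_voxel <- function(intensity) {
  if (anyNA(intensity) || any(intensity < 0))
    stop("intensity must be non-negative", call. = FALSE)
  intensity <- floor(intensity)
  lab <- ifelse(intensity <= 63, "hard", ifelse(intensity <= 100, "lsst", "hsst"))
  factor(lab, levels = c("hard", "lsst", "hsst"))
}

#' Quantify tissue volumes from an intensity grid
#'
#' Counts voxels per tissue label within an optional tooth mask and converts
#' counts to ml: volume = count * voxel_size_mm^3 / 1000. The mask (tooth vs
#' background delineation) is caller-supplied; automatic tooth detection is
#' out of scope.
#'
#' @param grid an [intensity_grid()].
#' @param mask optional logical array, same shape as the grid; `NULL` means
#'   all voxels belong to the tooth.
#' @return [tooth_volumes()] for the masked region.
#' @export
measure_volumes <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "intensity_grid"))
  vals <- grid$values
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(vals)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match grid shape ", paste(dim(vals), collapse = "x"),
           call. = FALSE)
    vals <- vals[as.logical(mask)]
  }
  ml_per_voxel <- grid$voxel_size_mm^3 / 1000
  lab <- if (length(vals)) classify_voxel(vals) else
    factor(character(), levels = c("hard", "lsst", "hsst"))
  n <- table(lab)
  tooth_volumes(hard = as.numeric(n[["hard"]]) * ml_per_voxel,
                hsst = as.numeric(n[["hsst"]]) * ml_per_voxel,
                lsst = as.numeric(n[["lsst"]]) * ml_per_voxel)
}

#' Number of voxels in a given volume
#'
#' How many isotropic voxels of edge `voxel_size_mm` make up `ml`
#' millilitres; at the 0.37-mm acquisition one ml is roughly 20,000 voxels.
#'
#' @param ml volume in millilitres.
#' @param voxel_size_mm voxel edge length in mm.
#' @return number of voxels (rounded to nearest integer).
#' @export
voxels_per_ml <- function(ml = 1, voxel_size_mm = 0.37) {
  round(ml * 1000 / voxel_size_mm^3)
}

#' Read / write an intensity grid as portable JSON
#'
#' Plain-text container: a JSON object with fields `dim` (3 integers),
#' `voxel_size_mm` and `values` (flattened column-major, as R stores arrays).
#'
#' @param path file path.
#' @return `read_intensity_grid()` returns an [intensity_grid()];
#'   `write_intensity_grid()` returns `path` invisibly.
#' @export
read_intensity_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("dim", "voxel_size_mm", "values"))
    if (is.null(obj[[f]])) stop("grid file missing field `", f, "`", call. = FALSE)
  intensity_grid(array(obj$values, dim = obj$dim), obj$voxel_size_mm)
}

#' @rdname read_intensity_grid
#' @param grid an [intensity_grid()] to serialize.
#' @export
write_intensity_grid <- function(grid, path) {
  stopifnot(inherits(grid, "intensity_grid"))
  jsonlite::write_json(
    list(dim = dim(grid$values), voxel_size_mm = grid$voxel_size_mm,
         values = as.vector(grid$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert measured volumes to a cohort-schema row
#'
#' Bridges voxel quantification to the cohort CSV schema: one participant-
#' tooth row ready for [write_cohort()].
#'
#' @param v a [tooth_volumes()] with all three volumes positive.
#' @param participant_id,sex,age_years,tooth_fdi row metadata.
#' @return one-row data frame in the cohort schema.
#' @export
volumes_to_row <- function(v, participant_id, sex, age_years, tooth_fdi) {
  stopifnot(inherits(v, "tooth_volumes"))
  validate_cohort(data.frame(
    participant_id = participant_id, sex = sex, age_years = age_years,
    tooth_fdi = tooth_fdi,
    hard_ml = v$hard, hsst_ml = v$hsst, lsst_ml = v$lsst))
}
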