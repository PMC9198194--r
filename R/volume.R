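#' Construct a volume object
#'
#' Wraps a 3D numeric array together with its physical voxel spacing and an
#' intensity-unit label. Volumes are indexed `(r, c, s)` (row, column, slice),
#' 1-based in R code; all displacement offsets elsewhere in the package are
#' expressed in this index space.
#'
#' @param data 3D numeric array, every axis at least 3 voxels (derivative
#'   kernels need a one-voxel margin). Non-finite values are rejected.
#' @param spacing numeric length-3, physical voxel size per axis in mm.
#'   Recorded for provenance; derivative kernels operate in index space.
#' @param intensity_units label for the intensity scale, e.g. `"HU"`.
#' @return An object of class `vt_volume`.
#' @export
vt_volume <- function(data, spacing = c(1, 1, 1), intensity_units = "arbitrary") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 3L))
    stop("every volume axis must have at least 3 voxels", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, intensity_units = intensity_units),
    class = "vt_volume"
  )
}

#' @export
print.vt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vt_volume> %d x %d x %d voxels, spacing %s mm, units: %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              x$intensity_units))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vt_volume <- function(x) dim(x$data)

#' Construct a region-of-interest mask
#'
#' @param mask 3D logical array, congruent with its paired volume, with at
#'   least one `TRUE` voxel.
#' @param threshold_hu the air-exclusion threshold already applied to this
#'   mask, or `NULL` if none.
#' @return An object of class `vt_mask`.
#' @export
vt_mask <- function(mask, threshold_hu = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  if (!any(mask)) stop("ROI mask has no TRUE voxel", call. = FALSE)
  structure(list(mask = mask, threshold_hu = threshold_hu), class = "vt_mask")
}

#' @export
print.vt_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<vt_mask> %d x %d x %d, %d ROI voxels%s\n",
              d[1], d[2], d[3], sum(x$mask),
              if (is.null(x$threshold_hu)) ""
              else sprintf(", air threshold %g HU applied", x$threshold_hu)))
  invisible(x)
}

#' @export
dim.vt_mask <- function(x) dim(x$mask)

check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$mask)))
    stop("volume and ROI mask shapes differ", call. = FALSE)
  invisible(TRUE)
}

#' Read a volume or mask from a NIfTI file
#'
#' Voxel spacing is taken from the file header. The reader refuses volumes
#' with fewer than 3 voxels on any axis rather than guessing an orientation
#' fix.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param intensity_units label recorded on the volume (NIfTI does not carry
#'   one); default `"HU"` for the CT use case.
#' @return A [vt_volume].
#' @export
read_volume <- function(path, intensity_units = "HU") {
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))  # drop NIfTI attributes
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  if (any(dim(arr) < 3L))
    stop("volume has an axis thinner than 3 voxels", call. = FALSE)
  spc <- RNifti::pixdim(img)[seq_len(3)]
  vt_volume(arr, spacing = spc, intensity_units = intensity_units)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param volume a [vt_volume] or [vt_mask].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "vt_mask")) {
    arr <- array(as.numeric(volume$mask), dim(volume$mask))
    spc <- c(1, 1, 1)
  } else {
    arr <- volume$data
    spc <- volume$spacing
  }
  img <- RNifti::asNifti(arr, pixdim = spc)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask from NIfTI
#'
#' Any voxel with value > 0.5 is treated as inside the ROI.
#'
#' @param path path to a `.nii`/`.nii.gz` mask.
#' @return A [vt_mask] with `threshold_hu = NULL`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L) stop("expected a 3D mask", call. = FALSE)
  vt_mask(arr > 0.5)
}

#' Remove air-like voxels from a region of interest
#'
#' CT colonography ROIs drawn around a polyp inevitably include lumen voxels
#' that are predominately air; those are discarded by intensity threshold
#' before any co-occurrence accumulation. Only the ROI shrinks: the full
#' volume, including sub-threshold voxels, remains available to the
#' derivative kernels so border voxels keep their true neighbourhood.
#'
#' The operation is idempotent and monotone: the output true-set is always a
#' subset of the input true-set.
#'
#' @param volume a [vt_volume].
#' @param mask a [vt_mask] congruent with `volume`.
#' @param threshold voxels with intensity strictly below this value are
#'   dropped from the ROI. Default -450 (HU), the air-exclusion level for
#'   CT colonography.
#' @return A new [vt_mask] with `threshold_hu` recorded. If no voxel
#'   survives, an error is raised (an empty ROI violates the mask contract).
#' @export
apply_air_threshold <- function(volume, mask, threshold = -450) {
  check_congruent(volume, mask)
  keep <- mask$mask & (volume$data >= threshold)
  if (!any(keep))
    stop("air threshold removed every ROI voxel (empty ROI)", call. = FALSE)
  vt_mask(keep, threshold_hu = threshold)
}
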