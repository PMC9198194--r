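#' Convert a 3-vector field to spherical coordinates
#'
#' Magnitude is the Euclidean norm. The azimuth is measured in the
#' (x, y)-plane from the +x axis via `acos(x / sqrt(x^2 + y^2))`, with `pi`
#' added when the y-component is negative, giving a range of `[0, 2*pi]`.
#' The polar angle is measured from the +z axis, `acos(z / |v|)`, range
#' `[0, pi]`.
#'
#' Degenerate voxels are resolved by convention, never by exception:
#' `x = y = 0` gives azimuth 0, and a zero-magnitude vector gives polar
#' angle 0. These conventions keep the voxel count of downstream texture
#' images intact and are deterministic.
#'
#' @param vx,vy,vz three congruent 3D arrays, the vector components. For the
#'   gradient domain these are the Sobel partials; for the Hessian domain
#'   they are the sorted eigenvalues `(l1, l2, l3)`.
#' @return An object of class `vt_spherical` with components `magnitude`,
#'   `azimuth`, `polar`.
#' @export
to_spherical <- function(vx, vy, vz) {
  if (!identical(dim(vx), dim(vy)) || !identical(dim(vx), dim(vz)))
    stop("vector component grids must be congruent", call. = FALSE)
  mag <- sqrt(vx^2 + vy^2 + vz^2)
  rxy <- sqrt(vx^2 + vy^2)
  az <- array(0, dim(vx))
  ok <- rxy > 0
  base <- acos(pmin(pmax(vx[ok] / rxy[ok], -1), 1))
  az[ok] <- ifelse(vy[ok] >= 0, base, pi + base)
  pol <- array(0, dim(vx))
  nz <- mag > 0
  pol[nz] <- acos(pmin(pmax(vz[nz] / mag[nz], -1), 1))
  structure(list(magnitude = mag, azimuth = az, polar = pol),
            class = "vt_spherical")
}

#' t-th root remapping of a magnitude grid
#'
#' Derivative magnitudes are heavy-tailed: most voxels sit in a narrow band
#' while edges produce a long upper tail, which makes a uniformly scaled
#' co-occurrence matrix sparse. The elementwise t-th root is a strictly
#' monotone (rank-preserving) one-to-one map that compresses the tail and
#' reduces skewness before uniform quantization.
#'
#' @param magnitude non-negative array.
#' @param t_root positive integer root; `t_root = 1` is the identity.
#' @return The remapped array.
#' @export
root_remap <- function(magnitude, t_root) {
  if (!is.numeric(t_root) || length(t_root) != 1L || t_root < 1 ||
      t_root != round(t_root))
    stop("`t_root` must be an integer >= 1", call. = FALSE)
  if (any(magnitude < 0)) stop("magnitude must be non-negative", call. = FALSE)
  if (t_root == 1) magnitude else magnitude^(1 / t_root)
}

#' Quantize an angle grid into equal bins
#'
#' Partitions `[0, period)` into `levels` equal half-open bins:
#' `floor(levels * angle / period)`, with the single boundary value
#' `angle == period` folded into the top bin `levels - 1`. Azimuths use
#' `period = 2*pi`, polar angles `period = pi`.
#'
#' @param angle array of angles in `[0, period]`.
#' @param levels integer number of bins, >= 1.
#' @param period angular period, `2*pi` (azimuth) or `pi` (polar).
#' @return Integer array of bin indices in `[0, levels - 1]`.
#' @export
quantize_angle <- function(angle, levels, period) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1 ||
      levels != round(levels))
    stop("`levels` must be an integer >= 1", call. = FALSE)
  tol <- 1e-9
  if (any(angle < -tol) || any(angle > period + tol))
    stop("angle outside [0, period]", call. = FALSE)
  a <- pmin(pmax(angle, 0), period)
  q <- floor(levels * a / period)
  q[a == period] <- levels - 1
  q <- pmin(q, levels - 1)  # guards floor at representable values just under period
  array(as.integer(q), dim(angle))
}

#' Quantize a magnitude grid by uniform min-max scaling over the ROI
#'
#' Uniform gray scaling: `floor((v - min) * levels / (max - min))` with the
#' maximum folded into the top level `levels - 1`. The minimum and maximum
#' are taken over ROI voxels only; values outside the ROI (which never enter
#' a co-occurrence pair) are clamped into the valid level range. A constant
#' ROI (`max == min`) quantizes to all zeros by documented contract.
#'
#' @param remapped non-negative array, typically the output of [root_remap()].
#' @param levels integer number of gray levels, >= 1.
#' @param roi a [vt_mask] congruent with `remapped`.
#' @return Integer array of levels in `[0, levels - 1]`.
#' @export
quantize_magnitude <- function(remapped, levels, roi) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1 ||
      levels != round(levels))
    stop("`levels` must be an integer >= 1", call. = FALSE)
  stopifnot(inherits(roi, "vt_mask"))
  if (!identical(dim(remapped), dim(roi$mask)))
    stop("magnitude grid and ROI mask shapes differ", call. = FALSE)
  v <- remapped[roi$mask]
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(array(0L, dim(remapped)))
  q <- floor((remapped - lo) * levels / (hi - lo))
  q[remapped == hi] <- levels - 1
  q <- pmin(pmax(q, 0), levels - 1)
  array(as.integer(q), dim(remapped))
}

#' Quantization configuration for a vector texture image
#'
#' @param t_root integer >= 1, root applied to the magnitude before scaling.
#' @param q_mag magnitude levels (ignored by angle-only VTI kinds).
#' @param q_azimuth azimuth levels.
#' @param q_polar polar-angle levels.
#' @return A `vt_quant` list.
#' @export
quant_config <- function(t_root = 2, q_mag = 1, q_azimuth = 8, q_polar = 4) {
  for (nm in c("t_root", "q_mag", "q_azimuth", "q_polar")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("`", nm, "` must be an integer >= 1", call. = FALSE)
  }
  structure(list(t_root = as.integer(t_root), q_mag = as.integer(q_mag),
                 q_azimuth = as.integer(q_azimuth),
                 q_polar = as.integer(q_polar)),
            class = "vt_quant")
}

#' Default quantization per VTI kind
#'
#' The defaults are the best-performing settings of the parameter studies:
#' GAV `(10, 5)` azimuth/polar levels with `t = 2`; TGV `(2, 10, 4)`
#' magnitude/azimuth/polar with `t = 2`; HAV `(5, 8)`; THV `(5, 3, 8)` with
#' `t = 4`. All are overridable through [quant_config()].
#'
#' @param kind one of `"GAV"`, `"TGV"`, `"HAV"`, `"THV"`.
#' @return A `vt_quant`.
#' @export
default_quant <- function(kind) {
  switch(match.arg(kind, c("GAV", "TGV", "HAV", "THV")),
         GAV = quant_config(t_root = 2, q_mag = 1, q_azimuth = 10, q_polar = 5),
         TGV = quant_config(t_root = 2, q_mag = 2, q_azimuth = 10, q_polar = 4),
         HAV = quant_config(t_root = 2, q_mag = 1, q_azimuth = 5, q_polar = 8),
         THV = quant_config(t_root = 4, q_mag = 5, q_azimuth = 3, q_polar = 8))
}

#' Assemble a quantized vector texture image (VTI)
#'
#' Builds one of the four VTI kinds from a spherical field:
#' * `GAV` / `HAV` — angle-only, channels (quantized azimuth, quantized
#'   polar);
#' * `TGV` / `THV` — full vector, channels (quantized magnitude, quantized
#'   azimuth, quantized polar), with the magnitude passed through
#'   [root_remap()] before min-max quantization over the ROI.
#'
#' The `G` kinds are meant for gradient-domain spherical fields, the `H`
#' kinds for Hessian-eigenvalue fields; the function itself is agnostic.
#'
#' @param kind `"GAV"`, `"TGV"`, `"HAV"` or `"THV"`.
#' @param spherical a `vt_spherical` from [to_spherical()].
#' @param cfg a `vt_quant`; defaults to [default_quant()] for the kind.
#' @param roi a [vt_mask] defining the magnitude scaling support.
#' @return An object of class `vt_vti` with fields `channels` (list of
#'   integer arrays), `levels` (per-channel level counts) and `kind`.
#' @export
build_vti <- function(kind, spherical, roi, cfg = default_quant(kind)) {
  kind <- match.arg(kind, c("GAV", "TGV", "HAV", "THV"))
  stopifnot(inherits(spherical, "vt_spherical"), inherits(cfg, "vt_quant"),
            inherits(roi, "vt_mask"))
  az <- quantize_angle(spherical$azimuth, cfg$q_azimuth, 2 * pi)
  pol <- quantize_angle(spherical$polar, cfg$q_polar, pi)
  if (kind %in% c("GAV", "HAV")) {
    channels <- list(azimuth = az, polar = pol)
    levels <- c(cfg$q_azimuth, cfg$q_polar)
  } else {
    mag <- quantize_magnitude(root_remap(spherical$magnitude, cfg$t_root),
                              cfg$q_mag, roi)
    channels <- list(magnitude = mag, azimuth = az, polar = pol)
    levels <- c(cfg$q_mag, cfg$q_azimuth, cfg$q_polar)
  }
  structure(list(channels = channels, levels = as.integer(levels),
                 kind = kind, quant = cfg),
            class = "vt_vti")
}

#' @export
print.vt_vti <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<vt_vti> kind %s, %d x %d x %d, channels (%s), levels (%s), %d states\n",
              x$kind, d[1], d[2], d[3],
              paste(names(x$channels), collapse = ", "),
              paste(x$levels, collapse = ", "), prod(x$levels)))
  invisible(x)
}
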