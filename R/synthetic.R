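# Gaussian-smoothed white noise: separable smoothing with sd = corr_length
# voxels along each axis, then rescaled to unit variance. The smoothing
# scale *is* the texture correlation length.
correlated_noise <- function(dims, corr_length) {
  a <- array(rnorm(prod(dims)), dims)
  radius <- max(1L, ceiling(3 * corr_length))
  w <- exp(-((-radius:radius)^2) / (2 * corr_length^2))
  w <- w / sum(w)
  for (ax in 1:3) a <- conv_axis(a, w, -radius:radius, ax)
  (a - mean(a)) / sd(a)
}

#' Specification of a synthetic lesion phantom
#'
#' Describes a spherical "lesion" of spatially correlated Gaussian texture
#' embedded in an air-valued background, emulating a soft-tissue polyp
#' surrounded by colonic lumen on CT. The two texture classes differ in
#' their noise correlation length and contrast amplitude, which propagates
#' into distinct gradient- and Hessian-domain statistics.
#'
#' @param shape integer length-3 volume dimensions (default `c(32, 32, 32)`).
#' @param class_label 0 or 1.
#' @param corr_length texture correlation length in voxels (> 0). Defaults:
#'   1.0 for class 0, 2.5 for class 1.
#' @param contrast_amplitude texture standard deviation in intensity units
#'   (HU-like). Defaults: 120 (class 0), 180 (class 1).
#' @param base_intensity mean lesion intensity (default 30, soft tissue HU).
#' @param background_value intensity outside the lesion (default -1000,
#'   air), below the -450 air threshold by construction.
#' @param lesion_radius lesion sphere radius in voxels; must leave a
#'   2-voxel margin inside `shape`.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return A `vt_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), class_label = 0,
                         corr_length = if (class_label == 0) 1.0 else 2.5,
                         contrast_amplitude = if (class_label == 0) 120 else 180,
                         base_intensity = 30, background_value = -1000,
                         lesion_radius = 12, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 3L))
    stop("`shape` must be 3 dimensions of at least 3 voxels", call. = FALSE)
  if (!class_label %in% c(0, 1)) stop("`class_label` must be 0 or 1",
                                      call. = FALSE)
  if (corr_length <= 0) stop("`corr_length` must be positive", call. = FALSE)
  if (lesion_radius + 2 > min(shape) / 2)
    stop("lesion must fit inside the volume with a 2-voxel margin",
         call. = FALSE)
  structure(list(shape = shape, class_label = as.integer(class_label),
                 corr_length = corr_length,
                 contrast_amplitude = contrast_amplitude,
                 base_intensity = base_intensity,
                 background_value = background_value,
                 lesion_radius = lesion_radius, seed = as.integer(seed)),
            class = "vt_phantom_spec")
}

#' Generate one phantom volume and its ROI mask
#'
#' The lesion is a sphere of correlated Gaussian texture (see
#' [phantom_spec()]); everything outside is set to the background (air)
#' value. The ROI mask is the lesion sphere itself, so applying the air
#' threshold afterwards keeps exactly the lesion voxels. The full volume,
#' including background, remains available to the derivative kernels, which
#' exercises the boundary handling of the real CT pipeline.
#'
#' @param spec a `vt_phantom_spec`.
#' @return List with elements `volume` ([vt_volume]), `mask` ([vt_mask]) and
#'   `label`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "vt_phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$shape
  tex <- correlated_noise(dims, spec$corr_length)
  ctr <- (dims + 1) / 2
  dist2 <- outer(outer((seq_len(dims[1]) - ctr[1])^2,
                       (seq_len(dims[2]) - ctr[2])^2, `+`),
                 (seq_len(dims[3]) - ctr[3])^2, `+`)
  inside <- dist2 <= spec$lesion_radius^2
  vol <- array(spec$background_value, dims)
  vol[inside] <- spec$base_intensity + spec$contrast_amplitude * tex[inside]
  list(volume = vt_volume(vol, intensity_units = "HU"),
       mask = vt_mask(inside),
       label = spec$class_label)
}

#' Generate a balanced two-class phantom cohort
#'
#' `n_per_class` lesions per class, with per-lesion jitter (lognormal,
#' about +/-10%) on the correlation length and contrast amplitude so no two
#' lesions are identical. Deterministic per `seed`. Setting
#' `null_cohort = TRUE` draws both classes from the class-0 texture
#' distribution (labels kept), giving a null cohort for permutation-style
#' checks.
#'
#' @param n_per_class lesions per class, >= 2.
#' @param base_spec template [phantom_spec()]; per-class defaults for
#'   `corr_length` / `contrast_amplitude` are applied on top of it.
#' @param seed integer master seed.
#' @param null_cohort if `TRUE`, class 1 lesions use class 0 texture
#'   parameters (labels become uninformative).
#' @return Tibble with columns `lesion_id`, `label`, `phantom` (list column
#'   of `list(volume, mask, label)`).
#' @export
make_cohort <- function(n_per_class, base_spec = phantom_spec(), seed = 1,
                        null_cohort = FALSE) {
  if (n_per_class < 2) stop("`n_per_class` must be >= 2", call. = FALSE)
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  seeds <- sample.int(.Machine$integer.max, n)
  jitter_cl <- exp(rnorm(n, 0, 0.1))
  jitter_amp <- exp(rnorm(n, 0, 0.1))
  phantoms <- lapply(seq_len(n), function(i) {
    cls <- if (null_cohort) 0L else labels[i]
    ref <- phantom_spec(class_label = cls)
    sp <- phantom_spec(
      shape = base_spec$shape, class_label = labels[i],
      corr_length = ref$corr_length * jitter_cl[i],
      contrast_amplitude = ref$contrast_amplitude * jitter_amp[i],
      base_intensity = base_spec$base_intensity,
      background_value = base_spec$background_value,
      lesion_radius = base_spec$lesion_radius, seed = seeds[i])
    make_phantom(sp)
  })
  tibble::tibble(
    lesion_id = sprintf("phantom_%03d", seq_len(n)),
    label = labels,
    phantom = phantoms
  )
}

#' Tiny worked-example fixtures with exhaustively enumerated VCMs
#'
#' Returns hand-sized vector texture images together with their
#' co-occurrence matrices enumerated by an explicit triple loop (the same
#' brute force used as the test oracle):
#' * `tiny2x2` — a 2 x 2 x 1 two-state image whose single-direction matrix
#'   can be checked by hand;
#' * `const4` — a constant 4 x 4 x 4 image, whose every direction matrix
#'   has a single nonzero cell.
#'
#' Each element carries `vti`, `roi`, and `vcms` (the 13 pre-symmetrization
#' count matrices, canonical order). The bundle is pure data and
#' regenerates identically on every call.
#'
#' @return Named list of fixtures.
#' @export
worked_example_fixtures <- function() {
  brute <- function(st, roi, u, d = 1) {
    dm <- dim(st)
    K <- max(st) + 1L
    cnt <- matrix(0L, K, K)
    for (r in seq_len(dm[1])) for (c in seq_len(dm[2]))
      for (s in seq_len(dm[3])) {
        p2 <- c(r, c, s) + d * u
        if (any(p2 < 1) || any(p2 > dm)) next
        if (!roi[r, c, s] || !roi[p2[1], p2[2], p2[3]]) next
        a <- st[r, c, s] + 1L; b <- st[p2[1], p2[2], p2[3]] + 1L
        cnt[a, b] <- cnt[a, b] + 1L
      }
    cnt
  }
  dirs <- canonical_directions()
  as_vti <- function(arr, levels, kind = "GAV") {
    # package channel-0 image as a single-channel-pair VTI stand-in:
    # use (value, 0) channels so state index equals the value
    structure(list(
      channels = list(azimuth = arr,
                      polar = array(0L, dim(arr))),
      levels = c(levels, 1L), kind = kind,
      quant = quant_config(q_azimuth = levels, q_polar = 1)),
      class = "vt_vti")
  }
  tiny_arr <- array(c(0L, 1L, 1L, 1L), c(2, 2, 1))
  tiny_roi <- vt_mask(array(TRUE, c(2, 2, 1)))
  const_arr <- array(0L, c(4, 4, 4))
  const_roi <- vt_mask(array(TRUE, c(4, 4, 4)))
  mk <- function(arr, roi, levels) {
    vcms <- lapply(seq_len(nrow(dirs)), function(i)
      brute(arr, roi$mask, dirs[i, ]))
    names(vcms) <- rownames(dirs)
    list(vti = as_vti(arr, levels), roi = roi, vcms = vcms)
  }
  list(tiny2x2 = mk(tiny_arr, tiny_roi, 2L),
       const4 = mk(const_arr, const_roi, 1L))
}
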