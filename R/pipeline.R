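#' Extract the 364 vector texture features of one lesion
#'
#' Runs the full per-lesion chain: air thresholding of the ROI, derivative
#' fields (Sobel gradient and/or Deriche Hessian eigenvalues, as the
#' requested VTI kinds demand), spherical conversion, quantization into
#' VTIs, the 13-direction VCM stack, and the 28 texture measures per
#' direction. Derivative kernels see the full volume including
#' sub-threshold voxels; only the ROI used for co-occurrence accumulation
#' shrinks.
#'
#' @param volume a [vt_volume].
#' @param mask a [vt_mask] congruent with `volume`.
#' @param kinds subset of `c("GAV", "TGV", "HAV", "THV")`.
#' @param quant named list of [quant_config()] per kind; missing kinds get
#'   [default_quant()].
#' @param d co-occurrence displacement in voxels (default 1).
#' @param threshold air-exclusion intensity (default -450 HU); `NULL`
#'   disables thresholding.
#' @param alpha Deriche scale for the Hessian domain (default 1).
#' @param lesion_id,label identification carried into the output rows.
#' @return Tibble with one row per requested kind: `lesion_id`, `label`,
#'   `vti_kind`, then the 364 feature columns.
#' @export
extract_lesion_features <- function(volume, mask,
                                    kinds = c("GAV", "TGV", "HAV", "THV"),
                                    quant = list(), d = 1, threshold = -450,
                                    alpha = 1, lesion_id = "lesion",
                                    label = NA_integer_) {
  kinds <- match.arg(kinds, c("GAV", "TGV", "HAV", "THV"), several.ok = TRUE)
  roi <- if (is.null(threshold)) mask
         else apply_air_threshold(volume, mask, threshold)
  sph <- list()
  if (any(kinds %in% c("GAV", "TGV"))) {
    g <- sobel_gradient(volume)
    sph$gradient <- to_spherical(g$dx, g$dy, g$dz)
  }
  if (any(kinds %in% c("HAV", "THV"))) {
    eig <- hessian_eigenvalues(deriche_second_derivatives(volume, alpha))
    sph$hessian <- to_spherical(eig$l1, eig$l2, eig$l3)
  }
  purrr::map_dfr(kinds, function(kind) {
    dom <- if (kind %in% c("GAV", "TGV")) "gradient" else "hessian"
    cfg <- quant[[kind]] %||% default_quant(kind)
    vti <- build_vti(kind, sph[[dom]], roi, cfg)
    stack <- compute_vcm_stack(vti, roi, d = d)
    fv <- feature_vector(stack, lesion_id, label)
    dplyr::bind_cols(fv[, c("lesion_id", "label")],
                     tibble::tibble(vti_kind = kind),
                     fv[, setdiff(names(fv), c("lesion_id", "label"))])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract features for a whole cohort
#'
#' Applies [extract_lesion_features()] to every lesion of a cohort tibble
#' (as produced by [make_cohort()], or assembled from [read_volume()] /
#' [read_mask()] calls). Per-lesion failures are caught, reported as
#' warnings, and the lesion skipped; the number of failures is attached as
#' the `n_failed` attribute.
#'
#' @param cohort tibble with columns `lesion_id`, `label` and `phantom`
#'   (list column of `list(volume, mask, ...)`).
#' @inheritParams extract_lesion_features
#' @param verbose print one line per lesion.
#' @return Tibble, one row per lesion and kind, wide feature columns.
#' @export
run_extract <- function(cohort, kinds = c("GAV", "TGV", "HAV", "THV"),
                        quant = list(), d = 1, threshold = -450, alpha = 1,
                        verbose = FALSE) {
  stopifnot(all(c("lesion_id", "label", "phantom") %in% names(cohort)))
  n_failed <- 0L
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    ph <- cohort$phantom[[i]]
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(
      extract_lesion_features(ph$volume, ph$mask, kinds = kinds,
                              quant = quant, d = d, threshold = threshold,
                              alpha = alpha,
                              lesion_id = cohort$lesion_id[i],
                              label = cohort$label[i]),
      error = function(e) {
        warning("lesion ", cohort$lesion_id[i], " failed: ",
                conditionMessage(e))
        n_failed <<- n_failed + 1L
        NULL
      })
    if (verbose)
      message(sprintf("extract %s: %.2fs", cohort$lesion_id[i],
                      proc.time()[["elapsed"]] - t0))
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "n_failed") <- n_failed
  res
}

#' Sweep quantization parameters and summarize classification performance
#'
#' For every row of a parameter grid, extracts the features of one VTI kind
#' under that quantization and cross-validates the classifier, reporting
#' mean and SD of the AUC — the same protocol as a quantization parameter
#' study.
#'
#' @param cohort cohort tibble (see [run_extract()]).
#' @param grid tibble with columns among `t_root`, `q_mag`, `q_azimuth`,
#'   `q_polar`; missing columns fall back to the kind's defaults.
#' @param kind the VTI kind being swept.
#' @param scheme,n_repeats,params,k_max,seed passed to [cross_validate()].
#' @inheritParams extract_lesion_features
#' @return The grid with `mean_auc` and `sd_auc` columns appended.
#' @export
run_sweep <- function(cohort, grid, kind = "THV",
                      scheme = "twofold_x100", n_repeats = 20,
                      params = rf_params(ntree = 500), k_max = 20, seed = 1,
                      d = 1, threshold = -450, alpha = 1) {
  if (nrow(grid) == 0) stop("empty parameter grid", call. = FALSE)
  base <- default_quant(kind)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, ])
    cfg <- quant_config(
      t_root = row$t_root %||% base$t_root,
      q_mag = row$q_mag %||% base$q_mag,
      q_azimuth = row$q_azimuth %||% base$q_azimuth,
      q_polar = row$q_polar %||% base$q_polar)
    feats <- run_extract(cohort, kinds = kind,
                         quant = stats::setNames(list(cfg), kind),
                         d = d, threshold = threshold, alpha = alpha)
    cv <- cross_validate(feats, scheme = scheme, n_repeats = n_repeats,
                         params = params, k_max = k_max, seed = seed)
    auc <- cv$summary[cv$summary$metric == "auc", ]
    tibble::tibble(mean_auc = auc$mean, sd_auc = auc$sd)
  })
  dplyr::bind_cols(grid, res)
}

#' Write the JSON sidecar describing a run's parameters
#'
#' Records the quantization configuration per kind, displacement, threshold,
#' Deriche scale and seeds, so every number in an output table can be traced
#' back to its configuration.
#'
#' @param path output JSON path.
#' @param kinds,quant,d,threshold,alpha,seed run parameters.
#' @return `path`, invisibly.
#' @export
write_run_sidecar <- function(path, kinds, quant = list(), d = 1,
                              threshold = -450, alpha = 1, seed = NULL) {
  cfg <- lapply(stats::setNames(kinds, kinds), function(k)
    unclass(quant[[k]] %||% default_quant(k)))
  jsonlite::write_json(
    list(vti_kinds = kinds, quant = cfg, displacement = d,
         threshold_hu = threshold, alpha = alpha, seed = seed,
         package_version = as.character(utils::packageVersion("vectex"))),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
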