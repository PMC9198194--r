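#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Pooled ROC curve of a cross-validation result
#'
#' @param object a `vt_cv` from [cross_validate()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.vt_cv <- function(object, ...) {
  auc <- object$summary$mean[object$summary$metric == "auc"]
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Pooled ROC (%s), mean AUC = %.3f", object$scheme, auc)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a vector co-occurrence matrix
#'
#' Displays the (log1p-scaled) pair counts over vector states for one
#' direction.
#'
#' @param vcm a `vt_vcm` from [compute_vcm()].
#' @return A ggplot.
#' @export
plot_vcm <- function(vcm) {
  stopifnot(inherits(vcm, "vt_vcm"))
  df <- tibble::tibble(
    v1 = as.vector(row(vcm$counts)) - 1L,
    v2 = as.vector(col(vcm$counts)) - 1L,
    count = as.vector(vcm$counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v2, y = .data$v1,
                                   fill = log1p(.data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log(1 + count)") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "state of displaced voxel", y = "state of anchor voxel",
      title = sprintf("VCM, direction (%s), d = %d",
                      paste(vcm$direction, collapse = ", "),
                      vcm$displacement)
    ) +
    ggplot2::theme_minimal()
}

#' Per-repetition AUC distribution of a twofold cross-validation
#'
#' @param cv a `vt_cv` with scheme `"twofold_x100"`.
#' @return A ggplot.
#' @export
plot_cv_auc <- function(cv) {
  stopifnot(inherits(cv, "vt_cv"))
  if (!"auc" %in% names(cv$per_repetition))
    stop("per-repetition AUCs are only available for the twofold scheme",
         call. = FALSE)
  ggplot2::ggplot(cv$per_repetition, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "#2166ac", colour = "white") +
    ggplot2::labs(x = "test AUC per repetition", y = "repetitions") +
    ggplot2::theme_minimal()
}
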