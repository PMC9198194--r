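#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per repetition (twofold scheme) or per held-out lesion
#' (leave-one-out), with the recorded metrics.
#'
#' @param x a `vt_cv` from [cross_validate()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.vt_cv <- function(x, ...) {
  x$per_repetition
}

#' One-row summary of a cross-validation result
#'
#' @param x a `vt_cv`.
#' @param ... unused.
#' @return A one-row tibble with `scheme`, mean/SD AUC, accuracy,
#'   sensitivity, specificity and the mean number of selected features.
#' @export
glance.vt_cv <- function(x, ...) {
  s <- x$summary
  pick <- function(m, col) s[[col]][s$metric == m]
  tibble::tibble(
    scheme = x$scheme,
    auc = pick("auc", "mean"), auc_sd = pick("auc", "sd"),
    accuracy = pick("accuracy", "mean"),
    sensitivity = pick("sensitivity", "mean"),
    specificity = pick("specificity", "mean"),
    n_selected_features = pick("n_selected_features", "mean"),
    seed = x$seed
  )
}
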