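#' Names of the 28 texture measures, in their fixed extraction order
#'
#' The first 14 are the classic Haralick co-occurrence statistics; the
#' remaining 14 are widely used extensions. The order is part of the feature
#' contract: feature vectors list all 28 measures for direction 1, then
#' direction 2, and so on. The set is a named constant so it can be swapped
#' wholesale if a different 28-measure battery is preferred.
#'
#' @format Character vector of length 28.
#' @export
measure_names <- c(
  "asm", "contrast", "correlation", "sum_of_squares_variance",
  "inverse_difference_moment", "sum_average", "sum_variance", "sum_entropy",
  "entropy", "difference_variance", "difference_entropy",
  "info_corr_1", "info_corr_2", "max_corr_coeff",
  "autocorrelation", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "dissimilarity", "maximum_probability",
  "inverse_difference", "inverse_difference_normalized",
  "inverse_difference_moment_normalized", "joint_average", "joint_variance",
  "inverse_variance", "difference_average", "marginal_entropy_sum"
)

log2z <- function(x) ifelse(x > 0, log2(x), 0)  # 0 * log 0 := 0 convention

#' Normalize a VCM into a joint probability matrix
#'
#' Divides the (symmetrized) counts by their total and precomputes the
#' marginals and the diagonal-sum / difference distributions on which the
#' texture measures are defined.
#'
#' @param m a `vt_vcm` with positive count total.
#' @return An object of class `vt_prob`: `p` (matrix summing to 1), `px` /
#'   `py` marginals, `p_sum` (distribution of `i + j`, support `2 .. 2K`),
#'   `p_diff` (distribution of `|i - j|`, support `0 .. K - 1`).
#' @export
normalize_vcm <- function(m) {
  stopifnot(inherits(m, "vt_vcm"))
  tot <- sum(m$counts)
  if (tot <= 0) stop("VCM has zero total count; cannot normalize",
                     call. = FALSE)
  p <- m$counts / tot
  K <- nrow(p)
  i <- row(p); j <- col(p)
  p_sum <- as.vector(tapply(p, i + j, sum))       # k = 2 .. 2K
  p_diff <- as.vector(tapply(p, abs(i - j), sum)) # k = 0 .. K-1
  structure(list(p = p, px = rowSums(p), py = colSums(p),
                 p_sum = p_sum, p_diff = p_diff, K = K),
            class = "vt_prob")
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), computed on the support of
# the marginals. Sentinel 0 when the support is trivial or the eigenproblem
# is numerically degenerate.
max_corr_coeff <- function(pm) {
  on <- pm$px > 0 & pm$py > 0
  if (sum(on) < 2) return(0)
  p <- pm$p[on, on, drop = FALSE]
  px <- pm$px[on]; py <- pm$py[on]
  Q <- (p / px) %*% (t(p) / py)
  ev <- tryCatch(eigen(Q, only.values = TRUE)$values, error = function(e) NULL)
  if (is.null(ev)) return(0)
  ev <- sort(Re(ev), decreasing = TRUE)
  if (length(ev) < 2 || !is.finite(ev[2])) return(0)
  sqrt(min(max(ev[2], 0), 1))
}

#' The 28 texture measures of a normalized co-occurrence matrix
#'
#' Computes, in the fixed order of [measure_names], the classic Haralick
#' statistics and their extensions. Gray-state indices run `1 .. K`.
#' Logarithms are base 2 (entropies in bits) with the `0 log 0 = 0`
#' convention. Measures undefined on degenerate matrices (correlation with
#' zero marginal variance, the information measures with zero marginal
#' entropy, a degenerate maximal-correlation eigenproblem) return a
#' documented sentinel of 0.
#'
#' @param pm a `vt_prob` from [normalize_vcm()].
#' @return Named numeric vector of length 28.
#' @export
texture_measures <- function(pm) {
  stopifnot(inherits(pm, "vt_prob"))
  p <- pm$p
  K <- pm$K
  i <- row(p); j <- col(p)
  px <- pm$px; py <- pm$py
  idx <- seq_len(K)
  mu_x <- sum(idx * px); mu_y <- sum(idx * py)
  var_x <- sum((idx - mu_x)^2 * px); var_y <- sum((idx - mu_y)^2 * py)

  ks <- 2:(2 * K)            # support of p_sum
  kd <- 0:(K - 1)            # support of p_diff
  p_sum <- pm$p_sum; p_diff <- pm$p_diff

  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (var_x > 0 && var_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / sqrt(var_x * var_y) else 0
  sum_sq_var <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum * log2z(p_sum))
  ent <- -sum(p * log2z(p))
  diff_avg <- sum(kd * p_diff)
  diff_var <- sum((kd - diff_avg)^2 * p_diff)
  diff_ent <- -sum(p_diff * log2z(p_diff))

  hx <- -sum(px * log2z(px))
  hy <- -sum(py * log2z(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  ic1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - ent))))
  mcc <- max_corr_coeff(pm)

  autoc <- sum(i * j * p)
  cdev <- i + j - mu_x - mu_y
  clus_prom <- sum(cdev^4 * p)
  clus_shade <- sum(cdev^3 * p)
  clus_tend <- sum(cdev^2 * p)
  dissim <- sum(abs(i - j) * p)
  max_prob <- max(p)
  invdiff <- sum(p / (1 + abs(i - j)))
  invdiff_n <- sum(p / (1 + abs(i - j) / K))
  idm_n <- sum(p / (1 + (i - j)^2 / K^2))
  joint_avg <- mu_x
  joint_var <- sum_sq_var
  offd <- i != j
  inv_var <- sum(p[offd] / (i[offd] - j[offd])^2)

  stats::setNames(
    c(asm, contrast, correlation, sum_sq_var, idm, sum_avg, sum_var, sum_ent,
      ent, diff_var, diff_ent, ic1, ic2, mcc,
      autoc, clus_prom, clus_shade, clus_tend, dissim, max_prob,
      invdiff, invdiff_n, idm_n, joint_avg, joint_var, inv_var, diff_avg,
      hx + hy),
    measure_names)
}

#' Per-lesion feature vector from a VCM stack
#'
#' Reduces each of the 13 direction matrices to its 28 texture measures and
#' concatenates them direction-major into a single 364-entry row. Feature
#' names have the form `<direction>__<measure>`, e.g. `d0_0_1__entropy`
#' (`m` prefixes a negative offset component). A direction whose matrix has
#' zero total (possible when the ROI is disconnected along it) contributes
#' the degenerate sentinel of 0 for all 28 measures, with a warning.
#'
#' @param stack a `vt_vcm_stack`.
#' @param lesion_id identifier string stored in the first column.
#' @param label optional binary class label (0 benign, 1 malignant).
#' @return A one-row tibble: `lesion_id`, `label`, then 364 feature columns.
#' @export
feature_vector <- function(stack, lesion_id, label = NA_integer_) {
  stopifnot(inherits(stack, "vt_vcm_stack"))
  vals <- purrr::imap(unclass(stack), function(vcm, dname) {
    v <- if (sum(vcm$counts) > 0) {
      texture_measures(normalize_vcm(vcm))
    } else {
      warning("VCM for direction ", dname,
              " is empty; emitting sentinel features")
      stats::setNames(rep(0, length(measure_names)), measure_names)
    }
    stats::setNames(v, paste0(dname, "__", names(v)))
  })
  row <- unlist(unname(vals), use.names = TRUE)
  dplyr::bind_cols(
    tibble::tibble(lesion_id = lesion_id, label = as.integer(label)),
    tibble::as_tibble(as.list(row))
  )
}

#' Canonical names of the 364 features
#'
#' @return Character vector of length 364, direction-major.
#' @export
feature_names <- function() {
  dirs <- rownames(canonical_directions())
  as.vector(t(outer(dirs, measure_names, paste, sep = "__")))
}

#' Write a wide-format feature table to CSV
#'
#' One row per lesion: `lesion_id`, `label`, then the 364 feature columns.
#'
#' @param features tibble as returned by [feature_vector()] /
#'   [run_extract()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_wide <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Write a long-format feature table to CSV
#'
#' Columns `lesion_id,direction,measure,value`, one row per lesion, direction
#' and measure.
#'
#' @inheritParams write_features_wide
#' @export
write_features_long <- function(features, path) {
  long <- features |>
    dplyr::select(-dplyr::any_of(c("label", "vti_kind"))) |>
    tidyr::pivot_longer(-"lesion_id", names_to = c("direction", "measure"),
                        names_sep = "__", values_to = "value")
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
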