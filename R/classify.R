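#' Default random-forest hyperparameters
#'
#' `ntree = 5000` trees; `mtry = NULL` means the engine default
#' (`sqrt(n_features)` for classification). Passed wherever a forest is fit.
#'
#' @param ntree number of trees.
#' @param mtry variables tried per split, or `NULL` for the engine default.
#' @return A named list.
#' @export
rf_params <- function(ntree = 5000, mtry = NULL) {
  list(ntree = as.integer(ntree), mtry = mtry)
}

fit_rf <- function(x, y, params) {
  args <- list(x = x, y = y, ntree = params$ntree)
  if (!is.null(params$mtry)) args$mtry <- params$mtry
  do.call(randomForest::randomForest, args)
}

# Split a feature tibble into (x matrix, y factor, ids).
dataset_parts <- function(features) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  meta <- intersect(c("lesion_id", "label", "vti_kind"), names(features))
  x <- as.matrix(features[setdiff(names(features), meta)])
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  y <- factor(features$label, levels = c(0, 1))
  if (anyNA(y) || nlevels(droplevels(y)) < 2)
    stop("both classes must be present with no missing labels", call. = FALSE)
  ids <- if ("lesion_id" %in% names(features)) features$lesion_id
         else as.character(seq_len(nrow(features)))
  list(x = x, y = y, ids = ids)
}

#' Stratified random twofold splits
#'
#' Randomly divides the lesions into equally sized training and testing
#' halves while maintaining the benign/malignant ratio in each half (per
#' class, sizes differ by at most one lesion, the training half receiving
#' the extra one). Repeated `n_repeats` times with independent permutations;
#' the whole sequence is reproducible from `seed`.
#'
#' @param features feature tibble with a `label` column.
#' @param n_repeats number of random splits (default 100).
#' @param seed integer seed for the split sequence.
#' @return List of `n_repeats` elements, each `list(train =, test =)` of row
#'   indices.
#' @export
stratified_twofold_splits <- function(features, n_repeats = 100, seed = 1) {
  parts <- dataset_parts(features)
  y <- parts$y
  if (any(table(y) < 2))
    stop("each class needs at least 2 lesions for a stratified split",
         call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_repeats), function(rep) {
    train <- integer(0)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      train <- c(train, idx[seq_len(ceiling(length(idx) / 2))])
    }
    list(train = sort(train),
         test = sort(setdiff(seq_along(y), train)))
  })
}

#' Empirical ROC curve, AUC and Youden operating point
#'
#' The ROC is swept over all distinct score thresholds (higher score =
#' more malignant) and the AUC computed by the trapezoidal rule, which
#' equals the normalized Mann-Whitney U statistic with ties counted half.
#' Accuracy, sensitivity and specificity are reported at the operating
#' point maximizing Youden's J = sensitivity + specificity - 1 (the highest
#' threshold on ties).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or a 2-level factor), positives = 1.
#' @return List with `auc`, `roc` (tibble of threshold/fpr/tpr), `accuracy`,
#'   `sensitivity`, `specificity`, `threshold`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) < 2)
    stop("ROC undefined: both classes must be present", call. = FALSE)
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # cumulative counts at each distinct threshold (score >= threshold)
  tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
  keep <- which(!duplicated(s, fromLast = TRUE))
  roc <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, tp[keep] / np),
    fpr = c(0, fp[keep] / nn)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  j <- roc$tpr - roc$fpr
  best <- which.max(j)
  sens <- roc$tpr[best]
  spec <- 1 - roc$fpr[best]
  acc <- (sens * np + spec * nn) / (np + nn)
  list(auc = auc, roc = roc, accuracy = acc, sensitivity = sens,
       specificity = spec, threshold = roc$threshold[best])
}

#' Rank features by random-forest GINI importance
#'
#' Fits one forest on the training rows only and orders all features by
#' decreasing mean decrease in GINI impurity. Test labels are never seen.
#'
#' @param features feature tibble (training rows only).
#' @param params forest hyperparameters, see [rf_params()].
#' @return Integer permutation of the feature column indices, most important
#'   first, with the feature names attached as names.
#' @export
gini_rank <- function(features, params = rf_params()) {
  parts <- dataset_parts(features)
  fit <- fit_rf(parts$x, parts$y, params)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(imp, decreasing = TRUE)
  stats::setNames(ord, colnames(parts$x)[ord])
}

#' Forward feature selection over a GINI importance ordering
#'
#' Starting from the 3 most important features and adding one at a time in
#' importance order, fits a forest on the training rows and scores the test
#' rows; returns the feature count `k` maximizing test AUC (smallest `k` on
#' ties) together with the metrics at that `k`.
#'
#' @param train,test feature tibbles (same columns).
#' @param ordering integer feature ordering from [gini_rank()].
#' @param params forest hyperparameters.
#' @param k_max largest feature count tried (default 50; the selection curve
#'   plateaus early at cohort scales of tens of lesions).
#' @return List with `best_k`, `best_auc`, `metrics` (accuracy, sensitivity,
#'   specificity at Youden's point), `scores` (test scores at `best_k`) and
#'   `auc_by_k`.
#' @export
forward_selection_rf <- function(train, test, ordering,
                                 params = rf_params(), k_max = 50) {
  ptr <- dataset_parts(train)
  pte <- dataset_parts(test)
  kmax <- min(k_max, ncol(ptr$x))
  ks <- seq(min(3L, kmax), kmax)
  aucs <- numeric(length(ks))
  scores_by_k <- vector("list", length(ks))
  for (ii in seq_along(ks)) {
    cols <- ordering[seq_len(ks[ii])]
    fit <- fit_rf(ptr$x[, cols, drop = FALSE], ptr$y, params)
    sc <- stats::predict(fit, pte$x[, cols, drop = FALSE],
                         type = "prob")[, "1"]
    scores_by_k[[ii]] <- sc
    aucs[ii] <- roc_auc(sc, pte$y)$auc
  }
  best <- which.max(aucs)  # which.max takes the first (smallest k) on ties
  res <- roc_auc(scores_by_k[[best]], pte$y)
  list(best_k = ks[best], best_auc = aucs[best],
       metrics = res[c("accuracy", "sensitivity", "specificity")],
       scores = scores_by_k[[best]],
       auc_by_k = stats::setNames(aucs, ks))
}

#' Cross-validated random-forest classification of texture features
#'
#' Two schemes:
#' * `"twofold_x100"` — `n_repeats` stratified random half/half splits. Per
#'   repetition, features are ranked by GINI importance on the training half
#'   and forward-selected against the test half; the repetition's best AUC
#'   and Youden-point metrics are recorded. The summary reports the mean and
#'   SD of each metric over repetitions.
#' * `"leave_one_out"` — each lesion in turn is held out; features are
#'   ranked on the remaining `n - 1`. Because one held-out lesion has no AUC
#'   of its own, the held-out scores are pooled across lesions for every
#'   candidate feature count `k` and one pooled AUC per `k` is computed; the
#'   reported result is the best pooled AUC (smallest `k` on ties).
#'
#' A master `seed` spawns one child seed per repetition (or held-out
#' lesion), so results are bit-reproducible.
#'
#' @param features feature tibble: `lesion_id`, `label`, feature columns.
#' @param scheme `"twofold_x100"` or `"leave_one_out"`.
#' @param n_repeats repetitions for the twofold scheme (default 100).
#' @param params forest hyperparameters, see [rf_params()].
#' @param k_max forward-selection cap.
#' @param seed master seed.
#' @return An object of class `vt_cv` with `scheme`, `per_repetition`
#'   (tibble), `summary` (tibble of metric mean/sd), `roc` (pooled ROC
#'   points) and bookkeeping fields.
#' @export
cross_validate <- function(features,
                           scheme = c("twofold_x100", "leave_one_out"),
                           n_repeats = 100, params = rf_params(),
                           k_max = 50, seed = 1) {
  scheme <- match.arg(scheme)
  parts <- dataset_parts(features)
  set.seed(seed)
  if (scheme == "twofold_x100") {
    splits <- stratified_twofold_splits(features, n_repeats, seed = seed)
    child <- sample.int(.Machine$integer.max, n_repeats)
    pooled_scores <- list()
    pooled_labels <- list()
    reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
      set.seed(child[r])
      tr <- features[splits[[r]]$train, ]
      te <- features[splits[[r]]$test, ]
      ordering <- gini_rank(tr, params)
      sel <- forward_selection_rf(tr, te, ordering, params, k_max)
      pooled_scores[[r]] <<- sel$scores
      pooled_labels[[r]] <<- te$label
      tibble::tibble(repetition = r, auc = sel$best_auc,
                     accuracy = sel$metrics$accuracy,
                     sensitivity = sel$metrics$sensitivity,
                     specificity = sel$metrics$specificity,
                     n_selected_features = sel$best_k)
    })
    roc <- roc_auc(unlist(pooled_scores), unlist(pooled_labels))$roc
    summary <- reps |>
      tidyr::pivot_longer(-"repetition", names_to = "metric") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                       .groups = "drop")
  } else {
    n <- nrow(features)
    child <- sample.int(.Machine$integer.max, n)
    kmax <- min(k_max, ncol(parts$x))
    ks <- seq(min(3L, kmax), kmax)
    score_mat <- matrix(NA_real_, n, length(ks))
    for (i in seq_len(n)) {
      set.seed(child[i])
      tr <- features[-i, ]
      ptr <- dataset_parts(tr)
      ordering <- gini_rank(tr, params)
      xi <- parts$x[i, , drop = FALSE]
      for (ii in seq_along(ks)) {
        cols <- ordering[seq_len(ks[ii])]
        fit <- fit_rf(ptr$x[, cols, drop = FALSE], ptr$y, params)
        score_mat[i, ii] <- stats::predict(fit, xi[, cols, drop = FALSE],
                                           type = "prob")[, "1"]
      }
    }
    auc_by_k <- apply(score_mat, 2, function(s)
      roc_auc(s, features$label)$auc)
    best <- which.max(auc_by_k)
    res <- roc_auc(score_mat[, best], features$label)
    reps <- tibble::tibble(lesion_id = parts$ids, label = features$label,
                           score = score_mat[, best])
    roc <- res$roc
    summary <- tibble::tibble(
      metric = c("auc", "accuracy", "sensitivity", "specificity",
                 "n_selected_features"),
      mean = c(res$auc, res$accuracy, res$sensitivity, res$specificity,
               ks[best]),
      sd = NA_real_)
  }
  structure(list(scheme = scheme, per_repetition = reps, summary = summary,
                 roc = roc, seed = seed, params = params, k_max = k_max),
            class = "vt_cv")
}

#' @export
print.vt_cv <- function(x, ...) {
  cat(sprintf("<vt_cv> scheme %s, seed %d\n", x$scheme, x$seed))
  print(x$summary)
  invisible(x)
}
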