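fast_rf <- rf_params(ntree = 200)

test_that("stratified twofold splits preserve class ratios and sizes", {
  # 63 lesions, 31 benign / 32 malignant
  ds <- make_test_dataset(n = 63, p = 4, seed = 2)
  ds$label <- c(rep(0L, 31), rep(1L, 32))
  splits <- stratified_twofold_splits(ds, n_repeats = 25, seed = 7)
  expect_length(splits, 25)
  for (sp in splits) {
    expect_equal(sort(c(sp$train, sp$test)), 1:63)
    for (half in sp) {
      tb <- table(factor(ds$label[half], levels = 0:1))
      expect_true(tb["0"] %in% 15:16)
      expect_equal(unname(tb["1"]), 16)
    }
    expect_lte(abs(length(sp$train) - length(sp$test)), 1)
  }
  # determinism
  expect_identical(splits, stratified_twofold_splits(ds, 25, seed = 7))

  tiny <- make_test_dataset(n = 4, p = 3, seed = 1)
  sp <- stratified_twofold_splits(tiny, 5, seed = 1)[[1]]
  expect_equal(table(tiny$label[sp$train]), table(tiny$label[sp$test]))

  onecls <- tiny; onecls$label <- 1L
  expect_error(stratified_twofold_splits(onecls, 1, 1), "class")
})

test_that("ROC/AUC agrees with pair counting and pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))

  set.seed(12)
  for (i in 1:5) {
    sc <- round(runif(30), 2)        # rounding forces ties
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    got <- roc_auc(sc, lab)
    expect_equal(got$auc, oracle_auc(sc, lab), tolerance = 1e-12)
    expect_equal(got$auc,
                 as.numeric(suppressMessages(
                   pROC::auc(lab, sc, direction = "<", levels = c(0, 1)))),
                 tolerance = 1e-12)
    expect_gte(got$sensitivity + got$specificity - 1, 0)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("GINI ranking surfaces a perfect predictor and buries a constant", {
  ds <- make_test_dataset(n = 30, p = 20, seed = 5)
  ds$f001 <- as.numeric(ds$label)          # perfect predictor
  ds$f002 <- 1                             # constant
  set.seed(99)
  ord <- gini_rank(ds, fast_rf)
  expect_equal(names(ord)[1], "f001")
  informative <- which(names(ord) == "f001")
  constant <- which(names(ord) == "f002")
  expect_gt(constant, informative)
  set.seed(99)
  expect_identical(ord, gini_rank(ds, fast_rf))
})

test_that("forward selection finds small informative subsets", {
  ds <- make_test_dataset(n = 40, p = 40, n_inf = 3, shift = 3, seed = 8)
  tr <- ds[1:20, ]    # alternating labels keep both halves balanced
  te <- ds[21:40, ]
  set.seed(21)
  ord <- gini_rank(tr, fast_rf)
  sel <- forward_selection_rf(tr, te, ord, fast_rf, k_max = 15)
  expect_lte(sel$best_k, 10)
  expect_gte(sel$best_auc, 0.95)

  # K_max = 3 evaluates exactly one model
  sel3 <- forward_selection_rf(tr, te, ord, fast_rf, k_max = 3)
  expect_length(sel3$auc_by_k, 1)
  expect_equal(sel3$best_k, 3)
})

test_that("feature selection never touches test labels", {
  ds <- make_test_dataset(n = 30, p = 25, n_inf = 2, shift = 2, seed = 14)
  tr <- ds[1:16, ]; te <- ds[17:30, ]
  set.seed(3); ord1 <- gini_rank(tr, fast_rf)
  te_perm <- te; te_perm$label <- sample(te$label)
  set.seed(3); ord2 <- gini_rank(tr, fast_rf)
  expect_identical(ord1, ord2)             # ordering is train-only
  # with a single candidate model the test scores cannot depend on test
  # labels, only the reported AUC can
  set.seed(4); a <- forward_selection_rf(tr, te, ord1, fast_rf, 3)
  set.seed(4); b <- forward_selection_rf(tr, te_perm, ord1, fast_rf, 3)
  expect_equal(unname(a$scores), unname(b$scores), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$best_auc, b$best_auc)))
})

test_that("cross-validation is reproducible and separates a separable dataset", {
  ds <- make_test_dataset(n = 28, p = 30, n_inf = 3, shift = 3, seed = 6)
  cv1 <- cross_validate(ds, "twofold_x100", n_repeats = 8,
                        params = fast_rf, k_max = 10, seed = 42)
  cv2 <- cross_validate(ds, "twofold_x100", n_repeats = 8,
                        params = fast_rf, k_max = 10, seed = 42)
  expect_identical(cv1$per_repetition, cv2$per_repetition)
  expect_identical(cv1$summary, cv2$summary)
  expect_equal(nrow(cv1$per_repetition), 8)
  expect_gte(glance(cv1)$auc, 0.9)
  expect_true(all(cv1$per_repetition$auc >= 0 & cv1$per_repetition$auc <= 1))

  td <- tidy(cv1)
  expect_s3_class(td, "tbl_df")
  expect_named(glance(cv1), c("scheme", "auc", "auc_sd", "accuracy",
                              "sensitivity", "specificity",
                              "n_selected_features", "seed"))
})

test_that("leave-one-out pools exactly n held-out predictions", {
  ds <- make_test_dataset(n = 14, p = 12, n_inf = 2, shift = 3, seed = 4)
  cv <- cross_validate(ds, "leave_one_out", params = fast_rf, k_max = 5,
                       seed = 9)
  expect_equal(nrow(cv$per_repetition), 14)
  expect_equal(cv$per_repetition$lesion_id, ds$lesion_id)
  expect_gte(glance(cv)$auc, 0.8)
  cv2 <- cross_validate(ds, "leave_one_out", params = fast_rf, k_max = 5,
                        seed = 9)
  expect_identical(cv$per_repetition, cv2$per_repetition)
})

test_that("plot methods return ggplot objects", {
  ds <- make_test_dataset(n = 16, p = 10, n_inf = 2, shift = 3, seed = 10)
  cv <- cross_validate(ds, "twofold_x100", n_repeats = 3, params = fast_rf,
                       k_max = 5, seed = 2)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(plot_cv_auc(cv), "ggplot")
  tv <- make_test_vti(c(5, 5, 5), c(2, 2), seed = 1)
  vcm <- compute_vcm(tv$vti, tv$roi, c(0, 0, 1))
  expect_s3_class(plot_vcm(vcm), "ggplot")
})
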