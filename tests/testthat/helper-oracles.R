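# Independent brute-force oracles used across the suite. These re-derive
# every checked quantity from first principles (explicit loops and direct
# summation) and never call the code paths they verify.

# Directed pair counts of a state array along offset u at displacement d,
# both endpoints required inside the ROI; explicit triple loop.
oracle_vcm <- function(st, roi, u, d = 1, nstate = max(st) + 1L) {
  dm <- dim(st)
  cnt <- matrix(0L, nstate, nstate)
  for (r in seq_len(dm[1])) for (cc in seq_len(dm[2]))
    for (s in seq_len(dm[3])) {
      p2 <- c(r, cc, s) + d * u
      if (any(p2 < 1) || any(p2 > dm)) next
      if (!roi[r, cc, s] || !roi[p2[1], p2[2], p2[3]]) next
      a <- st[r, cc, s] + 1L
      b <- st[p2[1], p2[2], p2[3]] + 1L
      cnt[a, b] <- cnt[a, b] + 1L
    }
  cnt
}

# Direct 3x3x3 Sobel convolution with edge replication, explicit loops.
# Kernel built as the outer product of difference and smoothing taps.
oracle_sobel <- function(a, axis) {
  dm <- dim(a)
  diffk <- c(-1, 0, 1)
  smoothk <- c(1, 2, 1)
  w <- function(ax, t) if (ax == axis) diffk[t + 2] else smoothk[t + 2]
  out <- array(0, dm)
  cl <- function(i, n) min(max(i, 1), n)
  for (r in seq_len(dm[1])) for (cc in seq_len(dm[2]))
    for (s in seq_len(dm[3])) {
      acc <- 0
      for (tr in -1:1) for (tc in -1:1) for (ts in -1:1) {
        acc <- acc + w(1, tr) * w(2, tc) * w(3, ts) *
          a[cl(r + tr, dm[1]), cl(cc + tc, dm[2]), cl(s + ts, dm[3])]
      }
      out[r, cc, s] <- acc
    }
  out
}

# Direct-summation texture measures on a symmetric probability matrix,
# written formula by formula over all cells (log base 2, 0 log 0 = 0).
oracle_measures <- function(p) {
  K <- nrow(p)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- 0; for (i in 1:K) mu_x <- mu_x + i * px[i]
  mu_y <- 0; for (j in 1:K) mu_y <- mu_y + j * py[j]
  var_x <- sum((1:K - mu_x)^2 * px); var_y <- sum((1:K - mu_y)^2 * py)
  psum <- numeric(2 * K); pdif <- numeric(K)
  for (i in 1:K) for (j in 1:K) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  acc <- list(asm = 0, contrast = 0, idm = 0, ent = 0, autoc = 0,
              prom = 0, shade = 0, tend = 0, dissim = 0, invd = 0,
              invdn = 0, idmn = 0, invvar = 0, ssv = 0, hxy1 = 0)
  for (i in 1:K) for (j in 1:K) {
    v <- p[i, j]
    acc$asm <- acc$asm + v^2
    acc$contrast <- acc$contrast + (i - j)^2 * v
    acc$idm <- acc$idm + v / (1 + (i - j)^2)
    acc$ent <- acc$ent - v * lg(v)
    acc$autoc <- acc$autoc + i * j * v
    dev <- i + j - mu_x - mu_y
    acc$prom <- acc$prom + dev^4 * v
    acc$shade <- acc$shade + dev^3 * v
    acc$tend <- acc$tend + dev^2 * v
    acc$dissim <- acc$dissim + abs(i - j) * v
    acc$invd <- acc$invd + v / (1 + abs(i - j))
    acc$invdn <- acc$invdn + v / (1 + abs(i - j) / K)
    acc$idmn <- acc$idmn + v / (1 + (i - j)^2 / K^2)
    if (i != j) acc$invvar <- acc$invvar + v / (i - j)^2
    acc$ssv <- acc$ssv + (i - mu_x)^2 * v
    acc$hxy1 <- acc$hxy1 - v * lg(px[i] * py[j])
  }
  sum_avg <- sum((2:(2 * K)) * psum[2:(2 * K)])
  sum_var <- sum(((2:(2 * K)) - sum_avg)^2 * psum[2:(2 * K)])
  sum_ent <- -sum(psum * lg(psum))
  diff_avg <- sum((0:(K - 1)) * pdif)
  diff_var <- sum(((0:(K - 1)) - diff_avg)^2 * pdif)
  diff_ent <- -sum(pdif * lg(pdif))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  hxy2 <- 0
  for (i in 1:K) for (j in 1:K)
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  corr <- if (var_x > 0 && var_y > 0)
    (acc$autoc - mu_x * mu_y) / sqrt(var_x * var_y) else 0
  ic1 <- if (max(hx, hy) > 0) (acc$ent - acc$hxy1) / max(hx, hy) else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - acc$ent))))
  on <- px > 0
  mcc <- if (sum(on) < 2) 0 else {
    pp <- p[on, on, drop = FALSE]
    Q <- matrix(0, nrow(pp), nrow(pp))
    pxo <- px[on]; pyo <- py[on]
    for (i in seq_len(nrow(pp))) for (j in seq_len(nrow(pp)))
      Q[i, j] <- sum(pp[i, ] * pp[j, ] / (pxo[i] * pyo))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(max(ev[2], 0), 1))
  }
  c(asm = acc$asm, contrast = acc$contrast, correlation = corr,
    sum_of_squares_variance = acc$ssv, inverse_difference_moment = acc$idm,
    sum_average = sum_avg, sum_variance = sum_var, sum_entropy = sum_ent,
    entropy = acc$ent, difference_variance = diff_var,
    difference_entropy = diff_ent, info_corr_1 = ic1, info_corr_2 = ic2,
    max_corr_coeff = mcc, autocorrelation = acc$autoc,
    cluster_prominence = acc$prom, cluster_shade = acc$shade,
    cluster_tendency = acc$tend, dissimilarity = acc$dissim,
    maximum_probability = max(p), inverse_difference = acc$invd,
    inverse_difference_normalized = acc$invdn,
    inverse_difference_moment_normalized = acc$idmn, joint_average = mu_x,
    joint_variance = acc$ssv, inverse_variance = acc$invvar,
    difference_average = diff_avg, marginal_entropy_sum = hx + hy)
}

# AUC by exhaustive pair counting (Mann-Whitney, ties half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Moment coefficient of skewness.
oracle_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# Random VTI with given per-channel levels; full-ROI companion mask.
make_test_vti <- function(dims, levels, seed = 1) {
  set.seed(seed)
  channels <- lapply(levels, function(L)
    array(sample.int(L, prod(dims), replace = TRUE) - 1L, dims))
  names(channels) <- paste0("ch", seq_along(levels))
  vti <- structure(list(channels = channels, levels = as.integer(levels),
                        kind = if (length(levels) == 2) "GAV" else "TGV",
                        quant = NULL),
                   class = "vt_vti")
  list(vti = vti, roi = vt_mask(array(TRUE, dims)))
}

# State array of a VTI computed independently (plain positional arithmetic).
oracle_state_array <- function(vti) {
  st <- vti$channels[[1]]
  for (k in seq_along(vti$levels)[-1])
    st <- st * vti$levels[k] + vti$channels[[k]]
  st
}

# Small random symmetric feature tibble for classifier tests: n lesions,
# p noise features, optionally n_inf informative ones (Gaussian class shift).
make_test_dataset <- function(n = 24, p = 30, n_inf = 0, shift = 2,
                              seed = 1) {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  if (n_inf > 0)
    x[, seq_len(n_inf)] <- x[, seq_len(n_inf)] + shift * label
  colnames(x) <- sprintf("f%03d", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(lesion_id = sprintf("L%02d", seq_len(n)), label = label),
    tibble::as_tibble(x))
}
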