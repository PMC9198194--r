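test_that("Sobel gradient of simple fields has the analytic form", {
  const <- vt_volume(array(7, c(5, 6, 7)))
  g <- sobel_gradient(const)
  expect_true(all(g$dx == 0) && all(g$dy == 0) && all(g$dz == 0))

  # linear ramp along columns: dy constant in the interior, dx = dz = 0
  dims <- c(5, 5, 5)
  ramp <- vt_volume(array(rep(seq_len(dims[2]), each = dims[1]), dims))
  g <- sobel_gradient(ramp)
  inner <- 2:4
  expect_true(all(g$dx[inner, inner, inner] == 0))
  expect_true(all(g$dz[inner, inner, inner] == 0))
  dy_in <- g$dy[inner, inner, inner]
  expect_true(all(dy_in == dy_in[1]) && dy_in[1] == 32)  # 2 * 16 smoothing gain
})

test_that("Sobel gradient matches the direct-convolution oracle voxelwise", {
  set.seed(7)
  a <- array(rnorm(125), c(5, 5, 5))
  g <- sobel_gradient(vt_volume(a))
  for (ax in 1:3) {
    got <- list(g$dx, g$dy, g$dz)[[ax]]
    expect_equal(got, oracle_sobel(a, ax), tolerance = 1e-12)
  }
})

test_that("derivative operators are linear", {
  set.seed(11)
  a <- array(rnorm(216), c(6, 6, 6))
  b <- array(rnorm(216), c(6, 6, 6))
  lin <- vt_volume(2 * a - 3 * b)
  gs <- sobel_gradient(lin)
  ga <- sobel_gradient(vt_volume(a)); gb <- sobel_gradient(vt_volume(b))
  expect_equal(gs$dx, 2 * ga$dx - 3 * gb$dx, tolerance = 1e-10)
  hs <- deriche_second_derivatives(lin)
  ha <- deriche_second_derivatives(vt_volume(a))
  hb <- deriche_second_derivatives(vt_volume(b))
  expect_equal(hs$ixy, 2 * ha$ixy - 3 * hb$ixy, tolerance = 1e-10)
  expect_equal(hs$izz, 2 * ha$izz - 3 * hb$izz, tolerance = 1e-10)
})

test_that("Deriche second derivatives respond correctly to polynomials", {
  const <- vt_volume(array(3, c(9, 9, 9)))
  h <- deriche_second_derivatives(const)
  for (comp in h) expect_lt(max(abs(comp)), 1e-10)

  # quadratic along rows on a long axis: ixx ~ 2 and flat deep inside,
  # iyy = izz = 0
  dims <- c(41, 7, 7)
  quad <- vt_volume(array(rep((seq_len(dims[1]))^2, times = prod(dims[2:3])),
                          dims))
  h <- deriche_second_derivatives(quad)
  core <- h$ixx[19:23, 4, 4]
  expect_true(all(core > 0))
  expect_equal(core, rep(2, 5), tolerance = 1e-3)
  expect_lt(max(abs(h$iyy[19:23, 4, 4])), 1e-8)
  expect_lt(max(abs(h$izz[19:23, 4, 4])), 1e-8)
  expect_error(deriche_second_derivatives(const, alpha = 0), "positive")
})

test_that("Deriche Hessian of a Gaussian bump matches finite differences", {
  dims <- c(15, 15, 15)
  ctr <- 8
  sig <- c(2.0, 2.6, 3.2)
  idx <- lapply(1:3, function(k) (seq_len(dims[k]) - ctr) / sig[k])
  bump <- exp(-outer(outer(idx[[1]]^2, idx[[2]]^2, `+`), idx[[3]]^2, `+`) / 2)
  h <- deriche_second_derivatives(vt_volume(bump * 100))
  expect_lt(h$ixx[ctr, ctr, ctr], 0)
  # central second differences at the peak, same 6 components
  a <- bump * 100
  fd <- c(
    a[ctr + 1, ctr, ctr] - 2 * a[ctr, ctr, ctr] + a[ctr - 1, ctr, ctr],
    a[ctr, ctr + 1, ctr] - 2 * a[ctr, ctr, ctr] + a[ctr, ctr - 1, ctr],
    a[ctr, ctr, ctr + 1] - 2 * a[ctr, ctr, ctr] + a[ctr, ctr, ctr - 1],
    (a[ctr + 1, ctr + 1, ctr] - a[ctr + 1, ctr - 1, ctr] -
       a[ctr - 1, ctr + 1, ctr] + a[ctr - 1, ctr - 1, ctr]) / 4,
    (a[ctr + 1, ctr, ctr + 1] - a[ctr + 1, ctr, ctr - 1] -
       a[ctr - 1, ctr, ctr + 1] + a[ctr - 1, ctr, ctr - 1]) / 4,
    (a[ctr, ctr + 1, ctr + 1] - a[ctr, ctr + 1, ctr - 1] -
       a[ctr, ctr - 1, ctr + 1] + a[ctr, ctr - 1, ctr - 1]) / 4)
  got <- c(h$ixx[ctr, ctr, ctr], h$iyy[ctr, ctr, ctr], h$izz[ctr, ctr, ctr],
           h$ixy[ctr, ctr, ctr], h$ixz[ctr, ctr, ctr], h$iyz[ctr, ctr, ctr])
  # compare unit-normalized 6-vectors: the smoothing of the exponential
  # kernel rescales but barely reshapes a wide bump's Hessian
  expect_equal(got / sqrt(sum(got^2)), fd / sqrt(sum(fd^2)),
               tolerance = 0.15)
  expect_equal(sign(got[1:3]), sign(fd[1:3]))
})

test_that("voxelwise eigenvalues are sorted and satisfy the symmetric identities", {
  # diagonal field
  dims <- c(3, 3, 3)
  mk <- function(v) array(v, dims)
  h <- structure(list(ixx = mk(1), iyy = mk(2), izz = mk(3),
                      ixy = mk(0), ixz = mk(0), iyz = mk(0)),
                 class = "vt_hessian")
  e <- hessian_eigenvalues(h)
  expect_equal(e$l1[1], 3); expect_equal(e$l2[1], 2); expect_equal(e$l3[1], 1)

  hz <- structure(lapply(stats::setNames(nm = c("ixx", "iyy", "izz", "ixy",
                                                "ixz", "iyz")),
                         function(...) mk(0)),
                  class = "vt_hessian")
  ez <- hessian_eigenvalues(hz)
  expect_true(all(ez$l1 == 0) && all(ez$l3 == 0))

  # random symmetric matrices: sorted order, trace and determinant identities
  set.seed(3)
  dims <- c(4, 4, 4)
  rnd <- function() array(rnorm(prod(dims)), dims)
  h <- structure(list(ixx = rnd(), iyy = rnd(), izz = rnd(),
                      ixy = rnd(), ixz = rnd(), iyz = rnd()),
                 class = "vt_hessian")
  e <- hessian_eigenvalues(h)
  expect_true(all(e$l1 >= e$l2 - 1e-12) && all(e$l2 >= e$l3 - 1e-12))
  tr <- h$ixx + h$iyy + h$izz
  expect_equal(e$l1 + e$l2 + e$l3, tr, tolerance = 1e-8)
  det_h <- h$ixx * (h$iyy * h$izz - h$iyz^2) -
    h$ixy * (h$ixy * h$izz - h$iyz * h$ixz) +
    h$ixz * (h$ixy * h$iyz - h$iyy * h$ixz)
  expect_equal(e$l1 * e$l2 * e$l3, det_h, tolerance = 1e-8)

  # spot-check 10 voxels against the dense symmetric eigensolver
  for (i in 1:10) {
    p <- arrayInd(i * 5, dims)
    m <- matrix(c(h$ixx[p], h$ixy[p], h$ixz[p],
                  h$ixy[p], h$iyy[p], h$iyz[p],
                  h$ixz[p], h$iyz[p], h$izz[p]), 3, 3)
    ref <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    expect_equal(c(e$l1[p], e$l2[p], e$l3[p]), ref, tolerance = 1e-9)
  }
})
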