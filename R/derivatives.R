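#' @importFrom stats rnorm runif sd setNames
NULL

# Shift a 3D array by k voxels along one axis with edge replication:
# out[i] = a[clamp(i + k, 1, n)]. All separable filters below are built
# from these shifts, so the boundary condition is replication throughout.
shift_rep <- function(a, k, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Correlate along one axis with weights w at integer offsets:
# out[i] = sum_j w[j] * a[i + offsets[j]]
conv_axis <- function(a, w, offsets, axis) {
  out <- array(0, dim(a))
  for (j in seq_along(w)) {
    if (w[j] == 0) next
    out <- out + w[j] * shift_rep(a, offsets[j], axis)
  }
  out
}

#' 3D Sobel gradient field
#'
#' Separable Sobel derivatives: the difference kernel `(-1, 0, 1)` on the
#' derivative axis and the smoothing kernel `(1, 2, 1)` on the two transverse
#' axes. Axis mapping is `x` = rows, `y` = columns, `z` = slices. Boundaries
#' are handled by edge replication, so a constant volume has an identically
#' zero gradient everywhere including the faces.
#'
#' @param volume a [vt_volume].
#' @return An object of class `vt_gradient` with components `dx`, `dy`, `dz`
#'   (3D arrays congruent with the volume).
#' @export
sobel_gradient <- function(volume) {
  stopifnot(inherits(volume, "vt_volume"))
  a <- volume$data
  diffk <- c(-1, 0, 1)
  smoothk <- c(1, 2, 1)
  off <- -1:1
  comp <- function(axis) {
    out <- a
    for (ax in 1:3) {
      w <- if (ax == axis) diffk else smoothk
      out <- conv_axis(out, w, off, ax)
    }
    out
  }
  structure(list(dx = comp(1), dy = comp(2), dz = comp(3)),
            class = "vt_gradient")
}

# Deriche exponential-family kernels, discretized on integer taps and
# truncated where the envelope falls below 1e-12. Normalization fixes the
# discrete response: smoothing has unit DC gain, the first-derivative kernel
# responds with 1 to a unit ramp, and the second-derivative kernel responds
# with 0 to constants and with 2 to n^2 (the continuous second derivative).
# The absolute scale cancels downstream in min-max magnitude quantization;
# only these relative normalizations matter.
deriche_kernels <- function(alpha) {
  radius <- max(3L, ceiling(-log(1e-12) / alpha))
  n <- -radius:radius
  env <- exp(-alpha * abs(n))
  smooth <- (alpha * abs(n) + 1) * env
  smooth <- smooth / sum(smooth)
  d1 <- n * env
  d1 <- d1 / sum(n * d1)             # unit response to ramp in = n
  b <- env
  u <- abs(n) * env
  h <- b - (sum(b) / sum(u)) * u     # zero DC
  h <- h * (2 / sum(n^2 * h))        # response 2 to in = n^2
  list(offsets = n, smooth = smooth, d1 = d1, d2 = h)
}

#' Second-order derivative (Hessian) field by Deriche filtering
#'
#' Computes the six unique entries of the voxelwise Hessian matrix with
#' separable exponential (Deriche-type, scale `alpha`) filters: the
#' second-derivative operator on a pure axis (smoothing on the other two),
#' and the composition of two first-derivative operators for the mixed
#' partials (smoothing on the remaining axis). Kernels are normalized so a
#' constant volume gives zero and a quadratic ramp `n^2` gives exactly 2 on
#' the matching diagonal entry. Boundaries use edge replication.
#'
#' @param volume a [vt_volume].
#' @param alpha positive smoothing scale of the exponential kernel
#'   (default 1; larger alpha = narrower kernel, less smoothing).
#' @return An object of class `vt_hessian` with components `ixx`, `iyy`,
#'   `izz`, `ixy`, `ixz`, `iyz`.
#' @export
deriche_second_derivatives <- function(volume, alpha = 1) {
  stopifnot(inherits(volume, "vt_volume"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("`alpha` must be a positive scalar", call. = FALSE)
  k <- deriche_kernels(alpha)
  a <- volume$data
  # ops[ax] in {"s","d1","d2"} per axis
  run <- function(ops) {
    out <- a
    for (ax in 1:3) {
      w <- switch(ops[ax], s = k$smooth, d1 = k$d1, d2 = k$d2)
      out <- conv_axis(out, w, k$offsets, ax)
    }
    out
  }
  structure(list(
    ixx = run(c("d2", "s", "s")),
    iyy = run(c("s", "d2", "s")),
    izz = run(c("s", "s", "d2")),
    ixy = run(c("d1", "d1", "s")),
    ixz = run(c("d1", "s", "d1")),
    iyz = run(c("s", "d1", "d1"))
  ), class = "vt_hessian")
}

#' Voxelwise eigenvalues of a symmetric Hessian field
#'
#' Solves the 3x3 symmetric eigenproblem at every voxel with the closed-form
#' trigonometric method (real symmetric matrices always have real
#' eigenvalues). Eigenvalues are sorted by signed value, `l1 >= l2 >= l3`.
#'
#' @param h a `vt_hessian` from [deriche_second_derivatives()].
#' @return An object of class `vt_eigen` with sorted eigenvalue grids
#'   `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(h) {
  stopifnot(inherits(h, "vt_hessian"))
  d <- dim(h$ixx)
  axx <- as.vector(h$ixx); ayy <- as.vector(h$iyy); azz <- as.vector(h$izz)
  axy <- as.vector(h$ixy); axz <- as.vector(h$ixz); ayz <- as.vector(h$iyz)

  p1 <- axy^2 + axz^2 + ayz^2
  q <- (axx + ayy + azz) / 3
  p2 <- (axx - q)^2 + (ayy - q)^2 + (azz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  # B = (A - qI)/p; detB/2 drives the phase. Guard p == 0 (scalar matrix).
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (axx - q) / safe_p; byy <- (ayy - q) / safe_p; bzz <- (azz - q) / safe_p
  bxy <- axy / safe_p; bxz <- axz / safe_p; byz <- ayz / safe_p
  detb <- bxx * (byy * bzz - byz^2) -
    bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  structure(list(l1 = array(l1, d), l2 = array(l2, d), l3 = array(l3, d)),
            class = "vt_eigen")
}
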