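#' The 13 canonical co-occurrence directions in 3D
#'
#' Of the 26 nearest-neighbour offsets of a voxel, half are the negations of
#' the other half, and a co-occurrence matrix along `-u` is the transpose of
#' the one along `u`; only 13 directions therefore carry information. The
#' canonical ordered set is returned as a 13 x 3 integer matrix of `(r, c, s)`
#' offsets, no two of which are negatives of each other.
#'
#' @return Integer matrix, 13 rows (directions) by 3 columns (offset
#'   components), with row names used as direction labels in feature names.
#' @export
canonical_directions <- function() {
  m <- rbind(
    c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
    c(0, 1, 1), c(1, 0, 1), c(1, 1, 0),
    c(-1, 1, 0), c(0, 1, -1), c(1, 0, -1),
    c(1, 1, 1), c(-1, 1, 1), c(1, 1, -1), c(-1, 1, -1)
  )
  storage.mode(m) <- "integer"
  rownames(m) <- apply(m, 1, function(u)
    paste0("d", paste(sub("^-", "m", as.character(u)), collapse = "_")))
  colnames(m) <- c("r", "c", "s")
  m
}

#' Map a vector state tuple to a matrix index
#'
#' Mixed-radix encoding with channel 1 most significant: for three channels
#' `index = ((v1 * L2) + v2) * L3 + v3`, for two `v1 * L2 + v2`. The map is
#' a bijection from the tuple lattice onto `0 .. prod(levels) - 1`.
#'
#' @param values integer vector (or matrix, one tuple per row) of channel
#'   values, each in `[0, level - 1]`.
#' @param levels integer vector of per-channel level counts.
#' @return Integer index (vector if `values` is a matrix), 0-based.
#' @export
state_index <- function(values, levels) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != length(levels))
    stop("values and levels lengths differ", call. = FALSE)
  for (k in seq_along(levels)) {
    if (any(values[, k] < 0 | values[, k] > levels[k] - 1))
      stop("state component out of range for channel ", k, call. = FALSE)
  }
  idx <- values[, 1]
  for (k in seq_along(levels)[-1]) idx <- idx * levels[k] + values[, k]
  as.integer(idx)
}

#' Invert [state_index()]
#'
#' @param index 0-based integer index vector.
#' @param levels integer vector of per-channel level counts.
#' @return Integer matrix, one decoded tuple per row.
#' @export
state_tuple <- function(index, levels) {
  if (any(index < 0 | index > prod(levels) - 1))
    stop("state index out of range", call. = FALSE)
  out <- matrix(0L, length(index), length(levels))
  rem <- as.integer(index)
  for (k in rev(seq_along(levels))) {
    out[, k] <- rem %% levels[k]
    rem <- rem %/% levels[k]
  }
  out
}

# Per-voxel 0-based state array of a VTI (mixed-radix over its channels).
vti_state_array <- function(vti) {
  d <- dim(vti$channels[[1]])
  st <- as.vector(vti$channels[[1]])
  for (k in seq_along(vti$levels)[-1])
    st <- st * vti$levels[k] + as.vector(vti$channels[[k]])
  array(as.integer(st), d)
}

#' Vector co-occurrence matrix along one direction
#'
#' Counts ordered pairs of vector states `(state(p), state(p + d * u))` over
#' all voxels `p` whose displaced partner lies inside the grid, with both
#' endpoints required to be inside the ROI (so thresholded air voxels never
#' contaminate the matrix). Out-of-grid partners are skipped; there is no
#' padding. By default the matrix is then symmetrized by adding its
#' transpose, the standard Haralick convention, which makes downstream
#' measures independent of scan orientation along the direction.
#'
#' @param vti a `vt_vti`.
#' @param roi a [vt_mask] congruent with the VTI.
#' @param direction integer length-3 offset with components in `{-1, 0, 1}`,
#'   typically a row of [canonical_directions()].
#' @param d positive integer displacement in voxels (default 1).
#' @param symmetrize add the transpose (default `TRUE`). Set `FALSE` to get
#'   the raw directed counts, whose total equals the number of admissible
#'   pairs.
#' @return An object of class `vt_vcm`: `counts` (square integer matrix of
#'   side `prod(levels)`), `direction`, `displacement`, `state_levels`,
#'   `n_pairs` (admissible pair count before symmetrization).
#' @export
compute_vcm <- function(vti, roi, direction, d = 1, symmetrize = TRUE) {
  stopifnot(inherits(vti, "vt_vti"), inherits(roi, "vt_mask"))
  direction <- as.integer(direction)
  if (length(direction) != 3L || any(abs(direction) > 1) ||
      all(direction == 0L))
    stop("`direction` must be a nonzero offset with components in {-1,0,1}",
         call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d))
    stop("`d` must be a positive integer", call. = FALSE)
  dm <- dim(vti$channels[[1]])
  if (!identical(dm, dim(roi$mask)))
    stop("VTI and ROI mask shapes differ", call. = FALSE)

  nstate <- prod(vti$levels)
  counts <- matrix(0L, nstate, nstate)
  off <- as.integer(d) * direction
  lo <- pmax(1L, 1L - off)
  hi <- pmin(dm, dm - off)
  if (any(hi < lo)) {
    warning("displacement too large for the volume: no admissible pairs")
    n_pairs <- 0L
  } else {
    st <- vti_state_array(vti)
    ir <- lo[1]:hi[1]; ic <- lo[2]:hi[2]; is <- lo[3]:hi[3]
    a <- st[ir, ic, is, drop = FALSE]
    b <- st[ir + off[1], ic + off[2], is + off[3], drop = FALSE]
    ok <- roi$mask[ir, ic, is, drop = FALSE] &
      roi$mask[ir + off[1], ic + off[2], is + off[3], drop = FALSE]
    n_pairs <- sum(ok)
    if (n_pairs == 0L) {
      warning("no admissible voxel pairs inside the ROI for this direction")
    } else {
      cell <- a[ok] * nstate + b[ok] + 1L
      counts <- matrix(tabulate(cell, nbins = nstate * nstate),
                       nstate, nstate, byrow = TRUE)
    }
  }
  if (symmetrize) counts <- counts + t(counts)
  structure(list(counts = counts, direction = direction,
                 displacement = as.integer(d),
                 state_levels = vti$levels, n_pairs = as.integer(n_pairs),
                 symmetrized = symmetrize),
            class = "vt_vcm")
}

#' Stack of VCMs over the 13 canonical directions
#'
#' @inheritParams compute_vcm
#' @return An object of class `vt_vcm_stack`: a named list of 13 `vt_vcm`
#'   objects in the canonical direction order.
#' @export
compute_vcm_stack <- function(vti, roi, d = 1, symmetrize = TRUE) {
  dirs <- canonical_directions()
  out <- lapply(seq_len(nrow(dirs)), function(i)
    compute_vcm(vti, roi, dirs[i, ], d = d, symmetrize = symmetrize))
  names(out) <- rownames(dirs)
  structure(out, class = "vt_vcm_stack")
}

#' Write a VCM as a plain-text matrix with a describing header
#'
#' @param vcm a `vt_vcm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcm <- function(vcm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# direction %s d %d levels %s",
                     paste(vcm$direction, collapse = " "),
                     vcm$displacement,
                     paste(vcm$state_levels, collapse = " ")), con)
  utils::write.table(vcm$counts, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
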