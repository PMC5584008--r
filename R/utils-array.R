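# Internal dense-array helpers: shifts, morphology, separable Gaussian
# convolution. All arrays are in the canonical (slice, down, right) order.

# Shift a 3-D array by integer offsets, filling exposed voxels with `fill`.
.shift3d <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, o) {
    # destination index i takes source i - o
    i <- seq_len(n)
    j <- i - o
    ok <- j >= 1L & j <= n
    list(dst = i[ok], src = j[ok])
  }
  z <- src(d[1], dz); y <- src(d[2], dy); x <- src(d[3], dx)
  if (!length(z$dst) || !length(y$dst) || !length(x$dst)) return(out)
  out[z$dst, y$dst, x$dst] <- a[z$src, y$src, x$src]
  out
}

# Integer offsets within a Euclidean ball of radius r (voxel-isotropic).
.ballOffsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- expand.grid(dz = s, dy = s, dx = s)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Binary dilation and erosion with a spherical structuring element
#'
#' Morphological dilation/erosion of a 3-D logical mask by a discrete
#' Euclidean ball of the given radius (in voxels, isotropic). Used to merge
#' air and tagged material into the colonic lumen and to build the
#' vicinity shell of tagged pools.
#'
#' @param mask 3-D logical array.
#' @param radius ball radius in voxels (default 3, the assumed thickness of
#'   the partial-volume layer).
#' @return 3-D logical array of the same shape.
#' @export
dilateMask <- function(mask, radius = 3) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, radius >= 0)
  off <- .ballOffsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | .shift3d(mask, off[i, 1], off[i, 2], off[i, 3], fill = FALSE)
  out
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, radius = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, radius >= 0)
  off <- .ballOffsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out & .shift3d(mask, off[i, 1], off[i, 2], off[i, 3], fill = TRUE)
  out
}

# 26-neighborhood adjacency: TRUE where any 26-neighbor of the voxel is in
# `mask` (the voxel itself not counted).
.adjacent26 <- function(mask) {
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | .shift3d(mask, off[i, 1], off[i, 2], off[i, 3], fill = FALSE)
  out
}

#' Label connected components of a 3-D mask
#'
#' Deterministic breadth-first connected-component labeling under 6- or
#' 26-connectivity. Labels are assigned in array scan order; 0 is
#' background.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6 (face neighbors) or 26 (all neighbors).
#' @return integer array of component labels, same shape as `mask`.
#' @export
labelComponents <- function(mask, connectivity = 6) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .cc_label3d(mask, as.integer(dim(mask)), as.integer(connectivity))
}

# Grow from seed voxels through `mask`: the union of connected components
# of `mask` containing at least one seed.
.growFromSeeds <- function(mask, seeds, connectivity = 6) {
  lab <- labelComponents(mask, connectivity)
  hit <- unique(lab[seeds & mask])
  hit <- hit[hit > 0L]
  if (!length(hit)) return(array(FALSE, dim(mask)))
  array(lab %in% hit, dim(mask))
}

# --- separable convolution with mirrored (symmetric) boundaries ----------

# Build the n x n convolution matrix for kernel k (odd length) with
# symmetric boundary reflection (edge voxel repeated).
.convMatrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    # (k * f)(p) = sum_o k[o] f(p - o)
    src <- seq_len(n) - o
    src[src < 1L] <- 1L - src[src < 1L]
    src[src > n] <- 2L * n + 1L - src[src > n]
    for (p in seq_len(n)) K[p, src[p]] <- K[p, src[p]] + k[o + r + 1L]
  }
  K
}

# Convolve a 3-D array along one axis with kernel k.
.convAxis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  K <- .convMatrix(dp[1], k)
  m <- K %*% m
  ap <- array(m, dp)
  inv <- order(perm)
  aperm(ap, inv)
}

# Sampled Gaussian (derivative) kernels, calibrated so that polynomial
# responses are exact: order 0 sums to 1, order 1 reproduces the slope of a
# ramp, order 2 reproduces the curvature of a parabola.
.gaussKernel <- function(sigma, order = 0) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(2L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0) return(g / sum(g))
  if (order == 1) {
    k <- -x / sigma^2 * g
    k <- k - mean(k)              # odd symmetry: already ~0
    return(k / sum(-x * k))
  }
  k <- (x^2 / sigma^2 - 1) / sigma^2 * g
  k <- k - mean(k)                # zero response to constants
  k / sum(x^2 * k / 2)            # unit response to x^2/2 curvature
}

# Gaussian smoothing of a 3-D array at isotropic scale sigma (voxels).
.gaussSmooth3d <- function(a, sigma) {
  k <- .gaussKernel(sigma, 0)
  for (ax in 1:3) a <- .convAxis(a, k, ax)
  a
}
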