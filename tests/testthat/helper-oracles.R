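# Independent brute-force oracles for small grids. These deliberately use
# naive loops so they share no code path with the implementation.

# 6- or 26-connected flood fill by explicit queue.
bruteFlood <- function(mask, seeds, conn = 6) {
  d <- dim(mask)
  reach <- array(FALSE, d)
  queue <- which(seeds & mask)
  reach[queue] <- TRUE
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    co <- arrayInd(p, d)
    for (i in seq_len(nrow(offs))) {
      q <- co + as.numeric(offs[i, ])
      if (any(q < 1) || any(q > d)) next
      qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
      if (mask[qi] && !reach[qi]) {
        reach[qi] <- TRUE
        queue <- c(queue, qi)
      }
    }
  }
  reach
}

# TRUE where any 26-neighbor is TRUE (naive loops).
bruteAdjacent26 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    zi <- pmin(pmax(seq_len(d[1]) + dz, 1), d[1])
    src <- array(FALSE, d)
    zz <- seq_len(d[1]) + dz; yy <- seq_len(d[2]) + dy; xx <- seq_len(d[3]) + dx
    okz <- zz >= 1 & zz <= d[1]; oky <- yy >= 1 & yy <= d[2]
    okx <- xx >= 1 & xx <= d[3]
    src[okz, oky, okx] <- mask[zz[okz], yy[oky], xx[okx]]
    out <- out | src
  }
  out
}

# Naive ball dilation / erosion (independent of the package operators).
bruteDilate <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, d)
  s <- -floor(r):floor(r)
  for (dz in s) for (dy in s) for (dx in s) {
    if (dz^2 + dy^2 + dx^2 > r^2) next
    src <- array(FALSE, d)
    zz <- seq_len(d[1]) - dz; yy <- seq_len(d[2]) - dy; xx <- seq_len(d[3]) - dx
    okz <- zz >= 1 & zz <= d[1]; oky <- yy >= 1 & yy <= d[2]
    okx <- xx >= 1 & xx <= d[3]
    src[okz, oky, okx] <- mask[zz[okz], yy[oky], xx[okx]]
    out <- out | src
  }
  out
}

bruteErode <- function(mask, r) !bruteDilate(!mask, r)

# Direct (non-separable) Gaussian smoothing with symmetric reflection,
# triple loop over kernel offsets: reference for the band smoothing.
bruteGaussSmooth <- function(a, sigma) {
  r <- max(2L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  d <- dim(a)
  refl <- function(i, n) { i[i < 1] <- 1 - i[i < 1]; i[i > n] <- 2 * n + 1 - i[i > n]; i }
  out <- array(0, d)
  for (oz in x) for (oy in x) for (ox in x) {
    w <- k1[oz + r + 1] * k1[oy + r + 1] * k1[ox + r + 1]
    out <- out + w * a[refl(seq_len(d[1]) - oz, d[1]),
                       refl(seq_len(d[2]) - oy, d[2]),
                       refl(seq_len(d[3]) - ox, d[3])]
  }
  out
}
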