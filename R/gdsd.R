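# Gaussian scale-space derivatives and the gradient-directional second
# derivative (GDSD): the second derivative of the smoothed image along
# the local gradient direction. Positive on the low-attenuation side of
# an edge, negative on the high side, zero at the edge center.

#' Gaussian scale-space partial derivatives
#'
#' First and second partial derivatives of a 3-D array by separable
#' convolution with sampled Gaussian-derivative kernels at scale `sigma`,
#' mirrored boundaries. Kernels are calibrated so a linear ramp yields
#' its exact slope and a parabola its exact curvature.
#'
#' @param vol an \linkS4class{HUVolume} or 3-D numeric array.
#' @param sigma Gaussian scale in voxels (> 0).
#' @return named list of 3-D arrays: `fz`, `fy`, `fx`, `fzz`, `fyy`,
#'   `fxx`, `fzy`, `fzx`, `fyx` (axes in canonical slice/down/right
#'   order).
#' @export
gaussianDerivatives <- function(vol, sigma = 1) {
  if (is(vol, "HUVolume")) vol <- vol@data
  stopifnot(length(dim(vol)) == 3L)
  if (sigma <= 0) stop("sigma must be positive")
  k0 <- .gaussKernel(sigma, 0)
  k1 <- .gaussKernel(sigma, 1)
  k2 <- .gaussKernel(sigma, 2)
  dAxis <- function(orders) {
    a <- vol
    for (ax in 1:3) {
      k <- switch(orders[ax] + 1L, k0, k1, k2)
      a <- .convAxis(a, k, ax)
    }
    a
  }
  list(fz = dAxis(c(1L, 0L, 0L)), fy = dAxis(c(0L, 1L, 0L)),
       fx = dAxis(c(0L, 0L, 1L)),
       fzz = dAxis(c(2L, 0L, 0L)), fyy = dAxis(c(0L, 2L, 0L)),
       fxx = dAxis(c(0L, 0L, 2L)),
       fzy = dAxis(c(1L, 1L, 0L)), fzx = dAxis(c(1L, 0L, 1L)),
       fyx = dAxis(c(0L, 1L, 1L)))
}

#' Gradient-directional second derivative
#'
#' Computes `f_ww = (fz^2 fzz + fy^2 fyy + fx^2 fxx + 2 fz fy fzy +
#' 2 fz fx fzx + 2 fy fx fyx) / |grad f|^2` on the volume after mapping
#' the HU window to [0, 1], with the Gaussian scale `sigma`. Where the
#' gradient magnitude falls below `eps` (flat regions carry no edge
#' information) the result is 0; residual excursions are clamped to
#' [-1, 1].
#'
#' @param vol an \linkS4class{HUVolume} or 3-D numeric array (HU).
#' @param sigma Gaussian scale in voxels (default 1).
#' @param huWindow HU window mapped to [0, 1].
#' @param eps gradient floor in normalized units per voxel.
#' @return 3-D numeric array `f_ww` in [-1, 1].
#' @export
computeGDSD <- function(vol, sigma = 1, huWindow = c(-1000, 1400),
                        eps = 1e-4) {
  if (is(vol, "HUVolume")) vol <- vol@data
  f <- (vol - huWindow[1]) / (huWindow[2] - huWindow[1])
  g <- gaussianDerivatives(f, sigma)
  grad2 <- g$fz^2 + g$fy^2 + g$fx^2
  num <- g$fz^2 * g$fzz + g$fy^2 * g$fyy + g$fx^2 * g$fxx +
    2 * (g$fz * g$fy * g$fzy + g$fz * g$fx * g$fzx + g$fy * g$fx * g$fyx)
  fww <- array(0, dim(f))
  ok <- grad2 > eps^2
  fww[ok] <- num[ok] / grad2[ok]
  pmin(pmax(fww, -1), 1)
}

#' Gradient magnitude at scale sigma
#'
#' First derivative along the gradient direction (the gradient
#' magnitude) of the Gaussian-smoothed volume, in HU per voxel; the
#' scaled derivative of the edge samples fed to [projectToArch()].
#'
#' @param vol an \linkS4class{HUVolume} or 3-D numeric array.
#' @param sigma Gaussian scale in voxels.
#' @return 3-D numeric array of gradient magnitudes.
#' @export
gradientMagnitude <- function(vol, sigma = 1) {
  if (is(vol, "HUVolume")) vol <- vol@data
  k0 <- .gaussKernel(sigma, 0)
  k1 <- .gaussKernel(sigma, 1)
  d1 <- function(axis) {
    a <- vol
    for (ax in 1:3) a <- .convAxis(a, if (ax == axis) k1 else k0, ax)
    a
  }
  sqrt(d1(1)^2 + d1(2)^2 + d1(3)^2)
}
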