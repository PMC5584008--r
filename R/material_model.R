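# The partial-volume material-fraction model. A two-material transition
# blurred by the scanner PSF follows an error-function intensity profile;
# plotting the scaled first derivative along the gradient direction
# against the intensity yields the arch curve. Orthogonal projection of a
# measured (intensity, scaled-derivative) sample onto the arch recovers
# the two material fractions; three pairwise transitions are averaged
# into three-material fractions.

#' The arch transition curve
#'
#' `arch(x) = (1/sqrt(2*pi)) * exp(-(erfinv(2x-1))^2)` for `x` in [0, 1]:
#' the scaled gradient magnitude across a Gaussian-blurred unit step as a
#' function of the mixture fraction. Computed via the equivalent closed
#' form `dnorm(qnorm(x))`. Symmetric about 1/2 with apex
#' `1/sqrt(2*pi)`; zero at both ends.
#'
#' @param x numeric vector of fractions in [0, 1].
#' @return non-negative numeric vector, same length as `x`.
#' @export
arch <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE) || anyNA(x))
    stop("arch is defined on [0, 1]")
  out <- dnorm(qnorm(x))
  out[x == 0 | x == 1] <- 0
  out
}

#' Project edge samples onto the arch curve
#'
#' Each sample pairs a CT attenuation `I` with the first derivative along
#' the gradient direction `gI`; the point `(I, theta * sigmaOmega * gI)`
#' is projected to the nearest point of the model curve
#' `(L + x (H - L), theta (H - L) arch(x))`, and the projected abscissa
#' gives the two material fractions. Attenuations outside `[L, H]` are
#' clamped to the nearest base before projection so fractions stay in
#' [0, 1]. The nearest point is found by dense curve sampling followed by
#' golden-section refinement; the search is deterministic.
#'
#' @param I numeric vector of attenuations (HU).
#' @param gI numeric vector of gradient-direction first derivatives
#'   (HU/voxel, magnitudes).
#' @param model a \linkS4class{TransitionModel}.
#' @param nGrid dense-sampling density (default 1024).
#' @return list with `x` (projected fraction of the high material),
#'   `tLow`, `tHigh`, and `IPrime` (projected attenuation).
#' @export
projectToArch <- function(I, gI, model, nGrid = 1024L) {
  stopifnot(is(model, "TransitionModel"))
  L <- model@L; H <- model@H
  if (H <= L) stop("degenerate transition model: H <= L")
  th <- model@theta
  xs <- pmin(pmax((I - L) / (H - L), 0), 1)
  ys <- model@sigmaOmega * abs(gI) / (H - L)   # theta applied via metric
  # minimize (x - xs)^2 + theta^2 (arch(x) - ys)^2 over x in [0, 1]
  grid <- seq(0, 1, length.out = as.integer(nGrid))
  ag <- arch(grid)
  n <- length(xs)
  best <- numeric(n)
  chunk <- max(1L, floor(4e6 / length(grid)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(xs[s:e], grid, "-")^2 +
      th^2 * (matrix(ag, e - s + 1L, length(grid), byrow = TRUE) - ys[s:e])^2
    best[s:e] <- grid[max.col(-d2, ties.method = "first")]
  }
  # vectorized golden-section refinement around the best grid cell
  h <- (grid[2] - grid[1])
  lo <- pmax(best - h, 0)
  hi <- pmin(best + h, 1)
  f <- function(x, i) (x - xs[i])^2 + th^2 * (arch(x) - ys[i])^2
  gr <- (sqrt(5) - 1) / 2
  i <- seq_len(n)
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1, i); f2 <- f(x2, i)
  for (it in 1:40) {
    take1 <- f1 <= f2
    hi[take1] <- x2[take1]; x2[take1] <- x1[take1]; f2[take1] <- f1[take1]
    x1[take1] <- hi[take1] - gr * (hi[take1] - lo[take1])
    f1[take1] <- f(x1[take1], i[take1])
    lo[!take1] <- x1[!take1]; x1[!take1] <- x2[!take1]; f1[!take1] <- f2[!take1]
    x2[!take1] <- lo[!take1] + gr * (hi[!take1] - lo[!take1])
    f2[!take1] <- f(x2[!take1], i[!take1])
  }
  x <- (lo + hi) / 2
  list(x = x, tLow = 1 - x, tHigh = x, IPrime = L + x * (H - L))
}

#' Estimate transition-model bases from material masks
#'
#' The bases of the three pairwise transitions are the mean attenuations
#' of the pure materials, measured on interior (1-voxel-eroded) masks to
#' avoid partial-volume contamination: air and tagged material from
#' their lumen masks, soft tissue from a reference wall mask. The
#' air-tissue pair reuses the air base as its low base and the tissue
#' base as its high base.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param masks named list of 3-D logical masks: `air`, `st`, `ftm`.
#' @param sigmaOmega gradient scale recorded on the models.
#' @param erode erosion radius applied to each mask (default 1).
#' @return named list of \linkS4class{TransitionModel}s `TA`, `TT`, `SA`.
#' @export
estimateBases <- function(vol, masks, sigmaOmega = 1, erode = 1) {
  a <- vol@data
  mean1 <- function(name) {
    m <- masks[[name]]
    if (is.null(m) || !any(m)) stop("empty mask for material '", name, "'")
    me <- if (erode > 0) erodeMask(m, erode) else m
    if (!any(me)) me <- m   # thin structures: fall back to the full mask
    mean(a[me])
  }
  muAir <- mean1("air"); muST <- mean1("st"); muFTM <- mean1("ftm")
  list(TA = TransitionModel("TA", muAir, muFTM, sigmaOmega),
       TT = TransitionModel("TT", muST, muFTM, sigmaOmega),
       SA = TransitionModel("SA", muAir, muST, sigmaOmega))
}

#' Calibrate the noise-invariance factor theta
#'
#' `theta` scales the derivative axis so that the empirical gradient apex
#' of a transition matches the model apex `(H - L) arch(1/2)`: it is the
#' ratio of the model apex to the 95th percentile of the scaled gradient
#' magnitudes over the transition samples, clamped to [0.1, 10]. At
#' least 50 samples are required.
#'
#' @param I numeric vector of sample attenuations (unused beyond length
#'   checking; kept for the sample-pair interface).
#' @param gI numeric vector of gradient-direction derivative magnitudes.
#' @param model a \linkS4class{TransitionModel}.
#' @return the calibrated theta (scalar).
#' @export
estimateTheta <- function(I, gI, model) {
  stopifnot(is(model, "TransitionModel"))
  if (length(gI) < 50L) stop("need at least 50 transition samples")
  apexEmp <- as.numeric(quantile(model@sigmaOmega * abs(gI), 0.95,
                                 names = FALSE, type = 7))
  if (apexEmp <= 0) stop("empirical gradient apex is zero")
  apexModel <- (model@H - model@L) * arch(0.5)
  min(10, max(0.1, apexModel / apexEmp))
}

#' Combine pairwise fractions into three-material fractions
#'
#' Averages the three pairwise transition fractions into per-voxel
#' fractions of air, soft tissue and tagged material:
#' `t_air = (tL_SA + tL_TA)/3`, `t_ST = (tH_SA + tL_TT)/3`,
#' `t_TR = 1 - t_air - t_ST` (equal to `(tH_TA + tH_TT)/3` because each
#' pair sums to 1). Inputs are two-column structures `(tLow, tHigh)`;
#' each pair must sum to 1 within 1e-9.
#'
#' @param pairTA,pairTT,pairSA lists with numeric `tLow` and `tHigh`.
#' @return list with numeric vectors `tAir`, `tST`, `tTR`.
#' @export
threeFractions <- function(pairTA, pairTT, pairSA) {
  for (p in list(TA = pairTA, TT = pairTT, SA = pairSA)) {
    if (max(abs(p$tLow + p$tHigh - 1)) > 1e-9)
      stop("pair fractions must sum to 1")
  }
  tAir <- (pairSA$tLow + pairTA$tLow) / 3
  tST <- (pairSA$tHigh + pairTT$tLow) / 3
  tTR <- 1 - tAir - tST
  list(tAir = tAir, tST = tST, tTR = tTR)
}
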