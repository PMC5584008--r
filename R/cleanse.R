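# Replacement rules and pipeline orchestration. Tissue-side transition
# voxels are rewritten by blending the tagged contribution toward the
# air base with the GDSD as weight (preserving pseudo-enhanced soft
# tissue); tagged material, AT layers and T-junction artifacts are
# rewritten from the three-material fractions so the tagged contribution
# collapses onto the air base. The new colonic wall is then smoothed.

#' Replacement values of the cleansing rules
#'
#' `sttReplacement` computes the tissue-side rule
#' `tL_TT * L_TT + tH_TT * (w * L_TA + (1 - w) * H_TA)` with blend
#' weight `w`; `tjunctionReplacement` computes the three-material rule
#' `t_air * L_TA + t_ST * L_TT + t_TR * L_TA`.
#'
#' @param tLTT,tHTT tissue-tagging pair fractions.
#' @param w blend weight in [-1, 1] (the GDSD, possibly apex-rescaled).
#' @param mTT,mTA \linkS4class{TransitionModel}s of the tissue-tagging
#'   and air-tagging pairs.
#' @param tAir,tST,tTR three-material fractions.
#' @return numeric vector of replacement attenuations (HU).
#' @export
sttReplacement <- function(tLTT, tHTT, w, mTT, mTA) {
  tLTT * mTT@L + tHTT * (w * mTA@L + (1 - w) * mTA@H)
}

#' @rdname sttReplacement
#' @export
tjunctionReplacement <- function(tAir, tST, tTR, mTA, mTT) {
  tAir * mTA@L + tST * mTT@L + tTR * mTA@L
}

#' Rewrite STT-layer voxels (tissue side)
#'
#' Applies the tissue-side rule to every STT voxel where the GDSD is
#' positive (low-attenuation side of the edge) and the attenuation
#' exceeds the pseudo-enhancement gate (default 100 HU). Other STT
#' voxels are unchanged. The GDSD enters as a blend weight after
#' rescaling by its own empirical edge apex (`blendApex`, the 99th
#' percentile of |GDSD| over the STT voxels when NULL), clamped to
#' [-1, 1], so that voxels on a strong edge move toward the air base.
#'
#' @param vol \linkS4class{HUVolume} to rewrite.
#' @param sttMask 3-D logical mask of STT voxels.
#' @param pairTT list with `tLow`, `tHigh` over `which(sttMask)`.
#' @param fww GDSD array from [computeGDSD()].
#' @param models list with \linkS4class{TransitionModel}s `TA`, `TT`.
#' @param gate attenuation gate in HU.
#' @param blendApex positive scalar or NULL (estimate from the mask).
#' @return list with `volume` and `replaced` (3-D logical).
#' @export
replaceSTT <- function(vol, sttMask, pairTT, fww, models, gate = 100,
                       blendApex = NULL) {
  if (is.null(models$TA) || is.null(models$TT))
    stop("replaceSTT requires TA and TT transition models")
  a <- vol@data
  idx <- which(sttMask)
  if (!length(idx))
    return(list(volume = vol, replaced = array(FALSE, dim(a))))
  if (is.null(blendApex)) {
    blendApex <- as.numeric(quantile(abs(fww[idx]), 0.99, names = FALSE))
    if (!is.finite(blendApex) || blendApex <= 0) blendApex <- 1
  }
  w <- pmin(pmax(fww[idx] / blendApex, -1), 1)
  sel <- fww[idx] > 0 & a[idx] > gate
  val <- sttReplacement(pairTT$tLow, pairTT$tHigh, w, models$TT, models$TA)
  a[idx[sel]] <- val[sel]
  replaced <- array(FALSE, dim(a))
  replaced[idx[sel]] <- TRUE
  list(volume = HUVolume(a, vol@spacing, vol@downAxis), replaced = replaced)
}

#' Rewrite tagged material, AT layers and T-junction artifacts
#'
#' Applies the three-material rule at every target voxel; the tagged and
#' air fractions both map onto the air base, so pure tagged voxels end
#' far below the soft-tissue range.
#'
#' @param vol \linkS4class{HUVolume} to rewrite.
#' @param targetMask 3-D logical mask (tagged ∪ AT ∪ T-junction).
#' @param fractions list with `tAir`, `tST`, `tTR` over
#'   `which(targetMask)`, each pair-consistent (sums to 1).
#' @param models list with `TA` and `TT` models.
#' @return list with `volume` and `replaced`.
#' @export
replaceTJunction <- function(vol, targetMask, fractions, models) {
  a <- vol@data
  idx <- which(targetMask)
  s <- fractions$tAir + fractions$tST + fractions$tTR
  if (length(idx) && max(abs(s - 1)) > 1e-9)
    stop("three-material fractions must sum to 1")
  if (length(idx))
    a[idx] <- tjunctionReplacement(fractions$tAir, fractions$tST,
                                   fractions$tTR, models$TA, models$TT)
  replaced <- array(FALSE, dim(a))
  replaced[idx] <- TRUE
  list(volume = HUVolume(a, vol@spacing, vol@downAxis), replaced = replaced)
}

#' Smooth the new colonic wall
#'
#' Gaussian smoothing (default scale 0.5) applied only within the band
#' of former tagged-wall interface voxels (the tagged-mask boundary
#' dilated by one voxel); outside the band the volume is bit-identical.
#'
#' @param vol cleansed \linkS4class{HUVolume}.
#' @param band 3-D logical mask of new-edge voxels.
#' @param sigma smoothing scale in voxels.
#' @return an \linkS4class{HUVolume}.
#' @export
enhanceWall <- function(vol, band, sigma = 0.5) {
  if (!any(band)) return(vol)
  sm <- .gaussSmooth3d(vol@data, sigma)
  a <- vol@data
  a[band] <- sm[band]
  HUVolume(a, vol@spacing, vol@downAxis)
}

# Project one pair over sample vectors.
.pairFractions <- function(I, gI, model, nGrid) {
  pr <- projectToArch(I, gI, model, nGrid)
  list(tLow = pr$tLow, tHigh = pr$tHigh)
}

#' Run the full electronic-cleansing pipeline
#'
#' Executes the nine stages in order: outside-air/lung/bone removal,
#' lumen detection, ambiguous-layer detection, AT-layer identification,
#' STT-layer detection, material-fraction approximation, GDSD
#' computation, the two replacement rules, and wall smoothing. The
#' returned volume equals the input everywhere outside the rewritten
#' lumen voxels and the wall band; the run is deterministic for a fixed
#' input and configuration.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list with `volume` (cleansed \linkS4class{HUVolume}) and `qc`
#'   (\linkS4class{QCReport}).
#' @export
runEC <- function(vol, cfg = cleanseConfig()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }
  thr <- cfg@thresholds
  pre <- preprocessVolume(vol, cfg)
  warns <- pre$warnings
  lum <- pre$lumen@data > 0L
  tick("preprocess")
  emptyQC <- function() new("QCReport",
    counts = c(lumen_voxels = sum(lum)),
    layers = data.frame(), bases = data.frame(),
    warnings = warns, timings = unlist(timings))
  if (!any(lum)) {
    warning("empty lumen; volume returned unchanged")
    return(list(volume = vol, qc = emptyQC()))
  }
  work <- pre$volume
  a <- work@data

  lay <- identifyATLayers(work, pre$lumen, cfg)
  stt <- detectSTTLayers(work, pre$lumen, lay$atMask, cfg)
  sttMask <- attr(stt, "mask")
  tick("layers")

  airMask <- (a < thr[["lumen_air_cut"]]) & lum
  ftmMask <- (a > thr[["ftm_cut"]]) & lum
  stMask <- a >= thr[["soft_tissue_min"]] & a <= thr[["soft_tissue_max"]] & lum
  if (!any(ftmMask)) {
    warning("no tagged material in lumen; volume returned unchanged")
    return(list(volume = vol, qc = emptyQC()))
  }
  models <- estimateBases(work, list(air = airMask, st = stMask,
                                     ftm = ftmMask),
                          sigmaOmega = cfg@sigmaOmega)
  gmag <- gradientMagnitude(work, cfg@sigmaOmega)
  if (cfg@thetaMode == "apex_match") {
    calib <- function(m, mask) {
      idx <- which(mask)
      if (length(idx) < 50L) return(m)
      initialize(m, theta = estimateTheta(a[idx], gmag[idx], m))
    }
    models$TA <- calib(models$TA, lay$ambMask)
    # tissue-tagging samples: the STT band away from air-facing edges
    # and identified AT layers, so the apex reflects the ST-FTM blur
    models$TT <- calib(models$TT,
                       sttMask & !dilateMask(airMask | lay$atMask, 2))
    thSA <- (models$TA@theta + models$TT@theta) / 2
    models$SA <- initialize(models$SA, theta = thSA)
  }
  tick("bases")

  fww <- computeGDSD(work, cfg@sigmaGDSD, cfg@huWindow, cfg@gradEps)
  tick("gdsd")

  tjMask <- lum & a >= thr[["at_layer_min"]] & a <= thr[["at_layer_max"]] &
    .adjacent26(airMask) & .adjacent26(stMask) & .adjacent26(ftmMask)
  targetMask <- ftmMask | lay$atMask | tjMask

  evalMask <- targetMask | sttMask
  idx <- which(evalMask)
  I <- a[idx]; gI <- gmag[idx]
  pTA <- .pairFractions(I, gI, models$TA, cfg@projectionSamples)
  pTT <- .pairFractions(I, gI, models$TT, cfg@projectionSamples)
  pSA <- .pairFractions(I, gI, models$SA, cfg@projectionSamples)
  frac <- threeFractions(pTA, pTT, pSA)
  tick("fractions")

  pick <- function(v, mask) v[match(which(mask), idx)]
  rs <- replaceSTT(work, sttMask,
                   list(tLow = pick(pTT$tLow, sttMask),
                        tHigh = pick(pTT$tHigh, sttMask)),
                   fww, models, gate = cfg@pehHuGate)
  # Precedence: STT voxels outside the tagged mask are governed solely by
  # the tissue-side rule (the gate may leave them untouched -- thin
  # soft-tissue layers stay); STT voxels inside the tagged mask fall
  # through to the three-material rule when the gate fails, so the
  # tagged-side partial-volume rim is still removed.
  tj <- targetMask & !rs$replaced & !(sttMask & !ftmMask)
  rt <- replaceTJunction(rs$volume, tj,
                         list(tAir = pick(frac$tAir, tj),
                              tST = pick(frac$tST, tj),
                              tTR = pick(frac$tTR, tj)),
                         models)
  tick("replace")

  bnd <- (dilateMask(ftmMask, 1) & !ftmMask) | (ftmMask & !erodeMask(ftmMask, 1))
  band <- dilateMask(bnd, 1)
  # compose replacements onto the original volume: voxels outside the
  # rewritten set and the wall band keep their input values bit-exactly
  out <- vol@data
  rew <- rs$replaced | rt$replaced
  out[rew] <- rt$volume@data[rew]
  outVol <- enhanceWall(HUVolume(out, vol@spacing, vol@downAxis), band,
                        cfg@sigmaWall)
  tick("wall")

  layers <- if (length(lay$components)) data.frame(
    id = vapply(lay$components, function(l) l@id, 0L),
    slice = vapply(lay$components, function(l) l@voxels[1, 1], 0L),
    cls = vapply(lay$components, function(l) l@cls, ""),
    voxels = vapply(lay$components, function(l) nrow(l@voxels), 0L),
    connH = vapply(lay$components, function(l) l@connHorizontal, 0L),
    connV = vapply(lay$components, function(l) l@connVertical, 0L)
  ) else data.frame()
  bases <- data.frame(
    pair = c("TA", "TT", "SA"),
    L = c(models$TA@L, models$TT@L, models$SA@L),
    H = c(models$TA@H, models$TT@H, models$SA@H),
    theta = c(models$TA@theta, models$TT@theta, models$SA@theta))
  qc <- new("QCReport",
    counts = c(lumen_voxels = sum(lum),
               ftm_before = sum(ftmMask),
               at_voxels = sum(lay$atMask),
               att_voxels = sum(lay$attMask),
               stt_voxels = sum(sttMask),
               tjunction_voxels = sum(tjMask),
               rewritten_stt = sum(rs$replaced),
               rewritten_three_material = sum(rt$replaced),
               wall_band = sum(band),
               ftm_after = sum(outVol@data > thr[["ftm_cut"]] & lum)),
    layers = layers, bases = bases, warnings = warns,
    timings = unlist(timings))
  list(volume = outVol, qc = qc)
}
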