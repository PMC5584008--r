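# Preprocessing: remove outside air, lungs and bones by seeded region
# growing, then detect the colonic lumen by merging thresholded air and
# tagged material under a spherical dilation. Removed structures are set
# to the soft-tissue floor (-100 HU) so that only colonic air and tagging
# survive the lumen thresholds.

.boundaryMask <- function(d) {
  m <- array(FALSE, d)
  m[c(1, d[1]), , ] <- TRUE
  m[, c(1, d[2]), ] <- TRUE
  m[, , c(1, d[3])] <- TRUE
  m
}

#' Remove air outside the body
#'
#' Region growing from seeds on the volume boundary through all voxels
#' below the soft-tissue floor (-100 HU). Grown voxels are set to
#' -100 HU. If no boundary voxel is below the floor the volume is
#' returned unchanged and a warning ("no outside air") is raised.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list with elements `volume` (modified \linkS4class{HUVolume})
#'   and `mask` (\linkS4class{LabelMap} of outside air).
#' @export
removeOutsideAir <- function(vol, cfg = cleanseConfig()) {
  thr <- cfg@thresholds
  a <- vol@data
  airish <- a < thr[["st_floor"]]
  seeds <- .boundaryMask(dim(a)) & airish
  if (!any(seeds)) {
    warning("no outside air: no boundary voxel below the soft-tissue floor")
    return(list(volume = vol, mask = LabelMap(array(0L, dim(a)),
                                              legend = c(`1` = "outside_air"))))
  }
  grown <- .growFromSeeds(airish, seeds, cfg@connectivity)
  a[grown] <- thr[["st_floor"]]
  list(volume = HUVolume(a, vol@spacing, vol@downAxis),
       mask = LabelMap(grown, legend = c(`1` = "outside_air")))
}

#' Remove the lungs
#'
#' Inside-air voxels (below -100 HU, outside the removed outside-air
#' mask) are counted in the first-10-slice and last-10-slice segments;
#' the segment with more inside air is taken as the lung segment (ties go
#' to the first). Region growing from the inside-air voxels of that
#' segment removes the lungs (set to -100 HU).
#'
#' @param vol an \linkS4class{HUVolume} with outside air removed.
#' @param outside \linkS4class{LabelMap} of outside air.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @param segmentSlices slices per end segment (default 10).
#' @return list with `volume`, `mask` (lung \linkS4class{LabelMap}) and
#'   `slices` (integer range of slices containing lung voxels).
#' @export
removeLungs <- function(vol, outside, cfg = cleanseConfig(),
                        segmentSlices = 10L) {
  thr <- cfg@thresholds
  a <- vol@data
  d <- dim(a)
  ns <- as.integer(segmentSlices)
  if (d[1] < 2L * ns) {
    ns <- max(1L, d[1] %/% 2L)
    warning("fewer than ", 2L * segmentSlices,
            " slices; end segments shrunk to ", ns)
  }
  inside <- (a < thr[["st_floor"]]) & !(outside@data > 0L)
  firstSeg <- seq_len(ns)
  lastSeg <- seq.int(d[1] - ns + 1L, d[1])
  n1 <- sum(inside[firstSeg, , ])
  n2 <- sum(inside[lastSeg, , ])
  empty <- LabelMap(array(0L, d), legend = c(`1` = "lung"))
  if (n1 == 0L && n2 == 0L)
    return(list(volume = vol, mask = empty, slices = integer()))
  seg <- if (n1 >= n2) firstSeg else lastSeg  # tie -> first segment
  seeds <- array(FALSE, d)
  seeds[seg, , ] <- inside[seg, , ]
  grown <- .growFromSeeds(inside, seeds, cfg@connectivity)
  a[grown] <- thr[["st_floor"]]
  lungSlices <- which(apply(grown, 1, any))
  list(volume = HUVolume(a, vol@spacing, vol@downAxis),
       mask = LabelMap(grown, legend = c(`1` = "lung")),
       slices = lungSlices)
}

#' Remove the bones
#'
#' Seeds are all voxels above the tagging cut (200 HU) within the slice
#' range of the lungs (which includes the ribs around them); region
#' growing over the above-200-HU set removes the connected bony
#' structures (set to -100 HU). Tagged colonic pools not connected to
#' those seeds are untouched.
#'
#' @param vol an \linkS4class{HUVolume} with lungs removed.
#' @param lungSlices integer vector of slices containing lungs.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list with `volume` and `mask` (bone \linkS4class{LabelMap}).
#' @export
removeBones <- function(vol, lungSlices, cfg = cleanseConfig()) {
  thr <- cfg@thresholds
  a <- vol@data
  d <- dim(a)
  bright <- a > thr[["ftm_cut"]]
  empty <- LabelMap(array(0L, d), legend = c(`1` = "bone"))
  if (!length(lungSlices) || !any(bright[lungSlices, , ]))
    return(list(volume = vol, mask = empty))
  seeds <- array(FALSE, d)
  seeds[lungSlices, , ] <- bright[lungSlices, , ]
  grown <- .growFromSeeds(bright, seeds, cfg@connectivity)
  a[grown] <- thr[["st_floor"]]
  list(volume = HUVolume(a, vol@spacing, vol@downAxis),
       mask = LabelMap(grown, legend = c(`1` = "bone")))
}

#' Detect the colonic lumen
#'
#' The lumen is the morphological dilation (spherical element, default
#' radius 3 voxels, the assumed partial-volume layer thickness) of the
#' union of thresholded air (below -600 HU) and tagged material (above
#' 200 HU). All later computation is restricted to this mask.
#'
#' @param vol an \linkS4class{HUVolume} after lung/bone removal.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return a \linkS4class{LabelMap} (1 = lumen). A warning is raised and
#'   an empty mask returned when no air or tagged voxels exist.
#' @export
detectColonicLumen <- function(vol, cfg = cleanseConfig()) {
  thr <- cfg@thresholds
  a <- vol@data
  core <- (a < thr[["lumen_air_cut"]]) | (a > thr[["ftm_cut"]])
  if (!any(core)) {
    warning("empty lumen: no air or tagged material after preprocessing")
    return(LabelMap(array(0L, dim(a)), legend = c(`1` = "lumen")))
  }
  LabelMap(dilateMask(core, cfg@dilationRadius), legend = c(`1` = "lumen"))
}

#' Run the full preprocessing chain
#'
#' Outside air, lungs and bones are removed in order and the colonic
#' lumen is detected. Steps are idempotent: applying the chain twice
#' equals applying it once.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list with `volume` (preprocessed), `lumen`
#'   (\linkS4class{LabelMap}), the intermediate masks `outsideAir`,
#'   `lungs`, `bones`, and `warnings`.
#' @export
preprocessVolume <- function(vol, cfg = cleanseConfig()) {
  warns <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  oa <- wh(removeOutsideAir(vol, cfg))
  lu <- wh(removeLungs(oa$volume, oa$mask, cfg))
  bo <- wh(removeBones(lu$volume, lu$slices, cfg))
  lum <- wh(detectColonicLumen(bo$volume, cfg))
  list(volume = bo$volume, lumen = lum, outsideAir = oa$mask,
       lungs = lu$mask, bones = bo$mask, warnings = warns)
}
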