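# Thin-layer analysis: detect ambiguous layers at the air-tagging
# interface, classify them into AT (artifact, to be removed) versus ATT
# (genuine thin soft tissue, to be preserved) by directional connectivity
# counting, and derive the tissue-tagging (STT) transition layers.

.thresholdMasks <- function(vol, lumen, cfg) {
  thr <- cfg@thresholds
  a <- vol@data
  lum <- lumen@data > 0L
  list(air = (a < thr[["lumen_air_cut"]]) & lum,
       ftm = (a > thr[["ftm_cut"]]) & lum,
       lumen = lum)
}

#' Detect ambiguous air-tagging layers
#'
#' From the boundary of air inside the lumen (voxels of intermediate
#' attenuation 26-adjacent to air), every edge voxel with no tagged
#' voxel among its 26 neighbors is removed; what remains are the
#' ambiguous layers, i.e. thin layers between air and tagged material
#' that could be either AT artifacts or genuine ATT soft tissue.
#'
#' @param vol preprocessed \linkS4class{HUVolume}.
#' @param lumen lumen \linkS4class{LabelMap}.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list of \linkS4class{LayerComponent} (class "ambiguous",
#'   26-connected), possibly empty. The union mask is attached as
#'   attribute `mask`.
#' @export
detectAmbiguousLayers <- function(vol, lumen, cfg = cleanseConfig()) {
  m <- .thresholdMasks(vol, lumen, cfg)
  # boundary of air: non-air lumen voxels hugging the air region (the
  # partial-volume band, or the first tagged row at a sharp interface)
  edge <- m$lumen & !m$air & .adjacent26(m$air)
  amb <- edge & .adjacent26(m$ftm)
  lab <- labelComponents(amb, 26L)
  comps <- .componentsFromLabels(lab, cls = "ambiguous")
  attr(comps, "mask") <- amb
  comps
}

.componentsFromLabels <- function(lab, cls) {
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(lab))
  lapply(seq_len(k), function(i) {
    sel <- lab[idx] == i
    new("LayerComponent", id = i,
        voxels = co[sel, , drop = FALSE], cls = cls)
  })
}

# First tagged-pool hit within `leap` voxels along one directed ray for
# every voxel (rows of vx); returns pool ids (0 = no hit). Rays leap over
# non-tagged voxels.
.probeHits <- function(vx, pools, leap, axis, step) {
  d <- dim(pools)
  hit <- integer(nrow(vx))
  p <- vx
  for (s in seq_len(leap)) {
    p[, axis] <- vx[, axis] + s * step
    ok <- hit == 0L & p[, axis] >= 1L & p[, axis] <= d[axis]
    if (!any(ok)) break
    v <- pools[p[ok, , drop = FALSE]]
    hh <- hit[ok]
    hh[v > 0L] <- v[v > 0L]
    hit[ok] <- hh
  }
  hit
}

# Directional connectivity counts of a voxel set against labeled pools.
# Horizontal: left and right along the horizontal in-slice axis (two
# rays); vertical: one ray downward (increasing down-axis index, toward
# the table). Returns per-pool horizontal/vertical counts.
.connCounts <- function(vx, pools, leap, downAxis) {
  horizAxis <- if (downAxis == 2L) 3L else 2L
  hits <- list(h1 = .probeHits(vx, pools, leap, horizAxis, -1L),
               h2 = .probeHits(vx, pools, leap, horizAxis, +1L),
               v  = .probeHits(vx, pools, leap, downAxis, +1L))
  ids <- sort(unique(c(hits$h1, hits$h2, hits$v)))
  ids <- ids[ids > 0L]
  h <- vapply(ids, function(i) sum(hits$h1 == i) + sum(hits$h2 == i), 0L)
  v <- vapply(ids, function(i) sum(hits$v == i), 0L)
  list(pools = ids, horizontal = as.integer(h), vertical = as.integer(v))
}

#' Classify an ambiguous layer as AT or ATT
#'
#' For every voxel of the layer, rays of up to `leap` voxels probe left
#' and right (horizontal) and downward toward the table (vertical); a ray
#' that reaches a voxel of an adjacent tagged pool counts one
#' connectivity for its orientation. A layer lying flat on a pool
#' accumulates vertical connectivity (AT artifact); a layer along the
#' bend of a pool accumulates horizontal connectivity (ATT soft tissue).
#' The layer is ATT iff some adjacent pool yields strictly more
#' horizontal than vertical connectivity; ties are AT.
#'
#' @param layer a \linkS4class{LayerComponent}.
#' @param ftmPools \linkS4class{LabelMap} of labeled tagged pools.
#' @param leap leaping distance in voxels (default 5).
#' @param downAxis in-slice axis pointing toward the table.
#' @return the \linkS4class{LayerComponent} with `cls` set to "AT" or
#'   "ATT" and connectivity counts filled against the decisive pool.
#' @export
classifyLayer <- function(layer, ftmPools, leap = 5L, downAxis = 2L) {
  pools <- if (is(ftmPools, "LabelMap")) ftmPools@data else ftmPools
  vx <- layer@voxels
  adj <- .connCounts(vx, pools, as.integer(leap), as.integer(downAxis))
  near <- .adjacent26(pools > 0L)
  touching <- any(near[vx] | pools[vx] > 0L)
  if (!length(adj$pools) && !touching)
    stop("layer has no adjacent tagged pool; classification undefined")
  cls <- "AT"
  bestH <- 0L; bestV <- 0L
  if (length(adj$pools)) {
    diff <- adj$horizontal - adj$vertical
    b <- which.max(diff)
    bestH <- adj$horizontal[b]; bestV <- adj$vertical[b]
    if (diff[b] > 0L) cls <- "ATT"
  }
  if (cls == "AT" && bestH > bestV) { bestH <- 0L; bestV <- 0L }
  initialize(layer, cls = cls, adjacentFTM = adj$pools,
             connHorizontal = bestH, connVertical = bestV)
}

#' Identify AT layers slice by slice
#'
#' Runs the ambiguous-layer classification per axial slice: ambiguous
#' voxels and tagged pools are labeled in 2-D (8-connectivity) within
#' each slice and every 2-D component is classified with
#' [classifyLayer()]. The 3-D AT and ATT masks are the unions of the
#' per-slice decisions. Components with no in-slice pool adjacency keep
#' the AT default (tie rule).
#'
#' @param vol preprocessed \linkS4class{HUVolume}.
#' @param lumen lumen \linkS4class{LabelMap}.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list with `components` (classified per-slice
#'   \linkS4class{LayerComponent}s), `atMask`, `attMask` (3-D logical)
#'   and `ambMask`.
#' @export
identifyATLayers <- function(vol, lumen, cfg = cleanseConfig()) {
  comps <- detectAmbiguousLayers(vol, lumen, cfg)
  amb <- attr(comps, "mask")
  m <- .thresholdMasks(vol, lumen, cfg)
  d <- dim(amb)
  atMask <- array(FALSE, d)
  attMask <- array(FALSE, d)
  out <- list()
  down <- vol@downAxis
  for (z in which(apply(amb, 1, any))) {
    sliceAmb <- array(amb[z, , ], c(1L, d[2], d[3]))
    sliceFtm <- array(m$ftm[z, , ], c(1L, d[2], d[3]))
    labA <- labelComponents(sliceAmb, 26L)
    labF <- labelComponents(sliceFtm, 26L)
    cc <- .componentsFromLabels(labA, cls = "ambiguous")
    for (comp in cc) {
      cl <- tryCatch(classifyLayer(comp, labF, cfg@leapDistance, down),
                     error = function(e) initialize(comp, cls = "AT"))
      vx <- cl@voxels
      vx[, 1] <- z
      cl@voxels <- vx
      if (cl@cls == "ATT") attMask[vx] <- TRUE else atMask[vx] <- TRUE
      out[[length(out) + 1L]] <- cl
    }
  }
  list(components = out, atMask = atMask, attMask = attMask, ambMask = amb)
}

#' Detect STT layers
#'
#' The vicinity of the tagged material -- a 3-voxel shell straddling the
#' pool boundary (two voxels outward, one inward) -- contains both AT
#' layers and the soft-tissue transition; removing the AT-layer voxels
#' leaves the STT layers, which include the ATT layers by construction.
#'
#' @param vol preprocessed \linkS4class{HUVolume}.
#' @param lumen lumen \linkS4class{LabelMap}.
#' @param atMask 3-D logical mask of identified AT-layer voxels.
#' @param cfg a \linkS4class{CleanseConfig}.
#' @return list of \linkS4class{LayerComponent} (class "STT"); the union
#'   mask is attached as attribute `mask`.
#' @export
detectSTTLayers <- function(vol, lumen, atMask, cfg = cleanseConfig()) {
  m <- .thresholdMasks(vol, lumen, cfg)
  shell <- dilateMask(m$ftm, 2) & !erodeMask(m$ftm, 1)
  stt <- shell & !m$air & !atMask
  lab <- labelComponents(stt, 26L)
  comps <- .componentsFromLabels(lab, cls = "STT")
  attr(comps, "mask") <- stt
  comps
}
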