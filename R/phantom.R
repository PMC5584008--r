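# Digital phantom generator. Scenes are built from analytic geometry
# (torso ellipse, colonic tube, gravity-flattened tagged pool, thin
# soft-tissue features), material fractions are measured by supersampling
# voxels that straddle an interface, and the volume is formed as the
# fraction-weighted material means plus pseudo-enhancement, blurred by a
# Gaussian point-spread function, with additive Gaussian noise. The
# accompanying truth carries per-voxel materials, subvoxel fractions and
# feature masks, so every pipeline stage has an oracle.

#' Construct a phantom specification
#'
#' Defaults describe a fecal-tagged CT colonography acquisition on a
#' 1-mm grid: material means air -950, soft tissue 20, tagged material
#' 710 HU (within the standard observed ranges), point-spread sigma 0.7
#' voxels, additive noise 20 HU, and pseudo-enhancement of soft tissue
#' near tagged material with amplitude 150 HU and decay length 1.5
#' voxels (so enhanced tissue above the 100 HU gate exists, as observed
#' clinically).
#'
#' @param scene one of "at_pool", "att_bend", "fold", "polyp",
#'   "tjunction", "torso", "combined".
#' @param shape grid shape (slice, down, right).
#' @param spacing voxel spacing in mm.
#' @param materials named means in HU (air, st, ftm, bone).
#' @param psfSigma point-spread Gaussian sigma (voxels).
#' @param noiseSigma additive Gaussian noise SD (HU).
#' @param pehAmplitude,pehDecay pseudo-enhancement amplitude (HU) and
#'   exponential decay length (voxels).
#' @param params named list of geometry overrides (advanced).
#' @param seed RNG seed for the noise.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(scene = "at_pool", shape = c(64L, 64L, 64L),
                        spacing = c(1, 1, 1),
                        materials = c(air = -950, st = 20, ftm = 710,
                                      bone = 1000),
                        psfSigma = 0.7, noiseSigma = 20,
                        pehAmplitude = 150, pehDecay = 1.5,
                        params = list(), seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      scene = scene, materials = materials, psfSigma = psfSigma,
      noiseSigma = noiseSigma, pehAmplitude = pehAmplitude,
      pehDecay = pehDecay, params = params, seed = as.integer(seed))
}

# Geometry parameters derived from the grid shape, overridable via
# spec@params.
.sceneParams <- function(spec) {
  d <- spec@shape
  n <- min(d[2], d[3])
  p <- list(
    cy = d[2] / 2 + 0.5, cx = d[3] / 2 + 0.5,   # torso center
    ry = 0.40 * d[2], rx = 0.45 * d[3],         # torso semi-axes
    cty = round(d[2] / 2), ctx = round(d[3] / 2),  # tube center
    Rt = round(0.22 * n),                       # tube radius
    foldH = max(5L, round(0.28 * 0.22 * n)),    # fold height
    foldZ = round(12 + (d[1] - 24) / 3), foldW = 1.5,
    polypZ = round(12 + 2 * (d[1] - 24) / 3),
    polypR = max(4L, round(0.18 * 0.22 * n)),
    lungZ = c(2.5, 9.5),                        # lungs in the first 10 slices
    distalZ = d[1] - 17.5)                      # distal tube segment (torso scene)
  p$yP <- p$cty                                 # pool surface through voxel centers
  p$xW <- round(p$ctx - 0.25 * p$Rt)            # thin-wall (ATT sheet) position
  utils::modifyList(p, spec@params)
}

# Vectorized material id at continuous points (voxel centers at integers).
# 1 air, 2 soft tissue, 3 tagged material, 4 bone.
.materialFun <- function(spec) {
  p <- .sceneParams(spec)
  scene <- spec@scene
  nz <- spec@shape[1]
  function(z, y, x) {
    # capped tube kept out of the first/last 10 slices: colonic air must
    # be enclosed and must not be mistaken for lung air by the
    # end-segment heuristic
    inz <- z >= 11.5 & z <= nz - 11.5
    torso <- ((y - p$cy) / p$ry)^2 + ((x - p$cx) / p$rx)^2 <= 1
    mat <- ifelse(torso, 2L, 1L)
    if (scene == "torso") {
      lungs <- (((z - 6) / 3.5)^2 + ((y - (p$cty - 6)) / 6.5)^2 +
                  ((x - (p$ctx - 10)) / 6.5)^2 <= 1) |
               (((z - 6) / 3.5)^2 + ((y - (p$cty - 6)) / 6.5)^2 +
                  ((x - (p$ctx + 10)) / 6.5)^2 <= 1)
      mat[torso & lungs & z >= p$lungZ[1] & z <= p$lungZ[2]] <- 1L
      ell <- ((y - p$cy) / p$ry)^2 + ((x - p$cx) / p$rx)^2
      rib <- ell >= 0.70 & ell <= 0.88 & z >= p$lungZ[1] & z <= p$lungZ[2]
      mat[torso & rib] <- 4L
      tube <- (y - p$cty)^2 + (x - p$ctx)^2 <= (0.5 * p$Rt)^2 &
        z >= p$distalZ & z <= nz - 10.5
      mat[torso & tube] <- ifelse(y[torso & tube] >= p$yP, 3L, 1L)
      return(mat)
    }
    tube <- (y - p$cty)^2 + (x - p$ctx)^2 <= p$Rt^2 & inz
    mat[torso & tube] <- 1L
    inTube <- torso & tube
    if (scene %in% c("at_pool", "fold", "polyp", "tjunction")) {
      mat[inTube & y >= p$yP] <- 3L
    } else if (scene %in% c("att_bend", "combined")) {
      pocket <- inTube & y >= p$yP & x >= p$xW + 0.5
      sheet <- inTube & y >= p$yP - 0.5 &
        x >= p$xW - 0.5 & x <= p$xW + 0.5
      ledge <- inTube & y >= p$yP - 0.5 & y <= p$yP + 2.5 &
        x > p$xW + 0.5 & x <= p$xW + 4.5
      mat[pocket] <- 3L
      mat[sheet | ledge] <- 2L
    }
    if (scene %in% c("fold", "combined")) {
      rad2 <- (y - p$cty)^2 + (x - p$ctx)^2
      fold <- inTube & abs(z - p$foldZ) <= p$foldW &
        rad2 >= (p$Rt - p$foldH)^2
      mat[fold] <- 2L
    }
    if (scene %in% c("polyp", "combined")) {
      pyc <- p$cty + sqrt(max(p$Rt^2 - (0.3 * p$Rt)^2, 0)) - p$polypR - 1
      pxc <- p$ctx + round(0.3 * p$Rt)
      polyp <- (z - p$polypZ)^2 + (y - pyc)^2 + (x - pxc)^2 <= p$polypR^2
      mat[inTube & polyp] <- 2L
    }
    if (scene == "tjunction") {
      wall <- inTube & abs(x - p$ctx) <= 1.5 & y >= p$yP - 5
      mat[wall] <- 2L
    }
    mat
  }
}

# Evaluate the material function on the voxel-center grid.
.materialGrid <- function(matFun, d) {
  co <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  array(matFun(co$z, co$y, co$x), d)
}

# Per-voxel material fractions: interface voxels (any face neighbor of a
# different material) are supersampled `super`^3 times; interior voxels
# are pure.
.materialFractions <- function(matFun, m0, super = 4L) {
  d <- dim(m0)
  diffNb <- array(FALSE, d)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    s <- .shift3d(m0, o[1], o[2], o[3], fill = -99L)
    diffNb <- diffNb | (s != -99L & s != m0)
  }
  fr <- lapply(1:4, function(k) array(as.numeric(m0 == k), d))
  idx <- which(diffNb)
  if (length(idx)) {
    co <- arrayInd(idx, d)
    offs <- (seq_len(super) - (super + 1) / 2) / super
    counts <- matrix(0, length(idx), 4)
    for (oz in offs) for (oy in offs) for (ox in offs) {
      m <- matFun(co[, 1] + oz, co[, 2] + oy, co[, 3] + ox)
      for (k in 1:4) counts[, k] <- counts[, k] + (m == k)
    }
    counts <- counts / super^3
    for (k in 1:4) fr[[k]][idx] <- counts[, k]
  }
  names(fr) <- c("air", "st", "ftm", "bone")
  fr
}

# Distance (in dilation rounds, 26-neighborhood) to the tagged-majority
# mask, up to maxd; Inf beyond.
.distToMask <- function(mask, maxd) {
  d <- array(Inf, dim(mask))
  d[mask] <- 0
  cur <- mask
  for (k in seq_len(maxd)) {
    nxt <- cur | .adjacent26(cur)
    ring <- nxt & !cur
    d[ring] <- k
    cur <- nxt
  }
  d
}

#' Generate a phantom volume with ground truth
#'
#' Builds the analytic scene geometry, measures subvoxel material
#' fractions by 4x-per-axis supersampling of interface voxels, forms the
#' image as fraction-weighted material means plus pseudo-enhancement of
#' soft tissue near tagged material, applies the Gaussian point-spread
#' blur, and adds seeded Gaussian noise.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with `volume` (\linkS4class{HUVolume}) and `truth`
#'   (\linkS4class{PhantomTruth}).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  .validateGeometry(spec)
  d <- spec@shape
  matFun <- .materialFun(spec)
  m0 <- .materialGrid(matFun, d)
  fr <- .materialFractions(matFun, m0)
  mu <- spec@materials
  base <- fr$air * mu[["air"]] + fr$st * mu[["st"]] +
    fr$ftm * mu[["ftm"]] + fr$bone * mu[["bone"]]

  ftmMaj <- fr$ftm > 0.5
  maxd <- ceiling(4 * spec@pehDecay)
  peh <- array(0, d)
  if (spec@pehAmplitude > 0 && any(ftmMaj)) {
    dist <- .distToMask(ftmMaj, maxd)
    w <- exp(-dist / spec@pehDecay)
    w[!is.finite(w)] <- 0
    w[ftmMaj] <- 0
    peh <- spec@pehAmplitude * w * fr$st
  }

  img <- base + peh
  if (spec@psfSigma > 0) img <- .gaussSmooth3d(img, spec@psfSigma)
  if (spec@noiseSigma > 0) {
    set.seed(spec@seed)
    img <- img + array(rnorm(prod(d), sd = spec@noiseSigma), d)
  }

  matLab <- array(max.col(cbind(as.vector(fr$air), as.vector(fr$st),
                                as.vector(fr$ftm), as.vector(fr$bone)),
                          ties.method = "first"), d)
  tAir <- fr$air
  tST <- fr$st + fr$bone   # bone is a solid non-tagged material
  tTR <- 1 - tAir - tST

  feats <- .truthFeatures(spec, fr, m0)
  truth <- new("PhantomTruth",
               materials = LabelMap(matLab,
                 legend = c(`1` = "air", `2` = "soft_tissue",
                            `3` = "ftm", `4` = "bone")),
               fractions = new("FractionField", tAir = tAir, tST = tST,
                               tTR = pmin(pmax(tTR, 0), 1)),
               atMask = feats$at, attMask = feats$attSheet,
               features = feats, peh = peh)
  list(volume = HUVolume(img, spec@spacing), truth = truth)
}

# Truth feature masks from the fraction arrays and scene geometry.
.truthFeatures <- function(spec, fr, m0) {
  p <- .sceneParams(spec)
  d <- spec@shape
  co <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  pure <- function(a) a >= 0.999
  ftmMaj <- fr$ftm > 0.5
  at <- fr$air > 0.01 & fr$ftm > 0.01 & fr$st < 0.5

  feats <- list(at = at, pureFTM = pure(fr$ftm),
                lumen = array((m0 == 1L | m0 == 3L) &
                  ((co$y - p$cty)^2 + (co$x - p$ctx)^2 <= (p$Rt + 1)^2), d))

  sheet <- array(FALSE, d)
  attCenter <- array(FALSE, d)
  if (spec@scene %in% c("att_bend", "combined")) {
    sheet <- array(co$x >= p$xW - 0.5 & co$x <= p$xW + 0.5 &
                     co$y >= p$yP - 0.5 &
                     (co$y - p$cty)^2 + (co$x - p$ctx)^2 <= p$Rt^2, d) &
      fr$st > 0.5
    airL <- .shift3d(fr$air > 0.5, 0, 0, 1, fill = FALSE)  # left neighbor is air
    ftmR <- .shift3d(ftmMaj, 0, 0, -1, fill = FALSE)       # right neighbor tagged
    attCenter <- sheet & pure(fr$st) & airL & ftmR
  }
  feats$attSheet <- sheet
  feats$attCenterline <- attCenter

  fold <- array(FALSE, d); foldSurf <- array(FALSE, d)
  if (spec@scene %in% c("fold", "combined")) {
    fold <- array(abs(co$z - p$foldZ) <= p$foldW &
                    (co$y - p$cty)^2 + (co$x - p$ctx)^2 >=
                      (p$Rt - p$foldH)^2 &
                    (co$y - p$cty)^2 + (co$x - p$ctx)^2 <= p$Rt^2, d) &
      fr$st > 0.5
    foldSurf <- fold & pure(fr$st) & .adjacent26(ftmMaj)
  }
  feats$fold <- fold
  feats$foldSurface <- foldSurf

  polyp <- array(FALSE, d); polypSurf <- array(FALSE, d)
  if (spec@scene %in% c("polyp", "combined")) {
    pyc <- p$cty + sqrt(max(p$Rt^2 - (0.3 * p$Rt)^2, 0)) - p$polypR - 1
    pxc <- p$ctx + round(0.3 * p$Rt)
    polyp <- array((co$z - p$polypZ)^2 + (co$y - pyc)^2 +
                     (co$x - pxc)^2 <= p$polypR^2, d) & fr$st > 0.5
    polypSurf <- polyp & pure(fr$st) & .adjacent26(ftmMaj)
  }
  feats$polyp <- polyp
  feats$polypSurface <- polypSurf

  if (spec@scene == "torso") {
    lungGeom <- (((co$z - 6) / 3.5)^2 + ((co$y - (p$cty - 6)) / 6.5)^2 +
                   ((co$x - (p$ctx - 10)) / 6.5)^2 <= 1) |
                (((co$z - 6) / 3.5)^2 + ((co$y - (p$cty - 6)) / 6.5)^2 +
                   ((co$x - (p$ctx + 10)) / 6.5)^2 <= 1)
    feats$lungs <- array(lungGeom, d) & fr$air > 0.5
    feats$ribs <- fr$bone > 0.5
    feats$distalPool <- array(co$z >= p$distalZ, d) & fr$ftm > 0.5
  }
  feats
}

# Geometry sanity: named features must fit inside the tube, otherwise
# the scene is rejected as colliding.
.validateGeometry <- function(spec) {
  p <- .sceneParams(spec)
  if (spec@scene %in% c("att_bend", "combined") &&
      abs(p$xW - p$ctx) >= p$Rt - 2)
    stop("phantom features collide: thin wall outside the tube")
  if (spec@scene %in% c("fold", "combined") && p$foldH >= p$Rt - 1)
    stop("phantom features collide: fold fills the tube")
  if (spec@scene %in% c("polyp", "combined") && 2 * p$polypR + 3 > p$Rt)
    stop("phantom features collide: polyp larger than the pool")
  invisible(TRUE)
}

#' Canonical test scenes
#'
#' The named scenes used throughout the test suite, each a
#' `generatePhantom()` result: `at_pool` (flat AT layer atop a tagged
#' pool), `att_bend` (thin soft-tissue layer along the bend of a pocket,
#' plus an open pool surface), `fold` (submerged fold ring), `polyp`
#' (submerged polyp), `tjunction` (soft-tissue wall crossing the pool
#' surface), `torso` (lungs and ribs for preprocessing), and `combined`
#' (pool + ATT sheet + fold + polyp).
#'
#' @param shape grid shape for every scene.
#' @param seed base RNG seed; scene i uses `seed + i`.
#' @param ... passed to [phantomSpec()] (e.g. `noiseSigma`).
#' @return named list of `list(volume, truth, spec)`.
#' @export
makeTestSuiteScenes <- function(shape = c(64L, 64L, 64L), seed = 1L, ...) {
  scenes <- c("at_pool", "att_bend", "fold", "polyp", "tjunction",
              "torso", "combined")
  out <- lapply(seq_along(scenes), function(i) {
    sp <- phantomSpec(scene = scenes[i], shape = shape,
                      seed = seed + i, ...)
    c(generatePhantom(sp), list(spec = sp))
  })
  names(out) <- scenes
  out
}
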