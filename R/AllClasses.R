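#' @import methods
#' @importFrom stats dnorm qnorm quantile rnorm
#' @importFrom utils modifyList
#' @useDynLib ecleanse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' HUVolume: a calibrated 3-D CT volume
#'
#' A dense 3-D grid of CT attenuations in Hounsfield units, with voxel
#' spacing and a declared "down" axis. Arrays are kept in the canonical
#' axis order (slice, down, right); the down axis is the in-slice axis
#' whose increasing index points toward the scanner table. The table is
#' assumed at the image bottom, so gravity-settled tagged pools have their
#' flat surface perpendicular to the down axis.
#'
#' @slot data 3-D numeric array of HU values (all finite).
#' @slot spacing numeric length-3, voxel size in mm as (slice, down, right).
#' @slot downAxis integer, index of the down axis (2 in canonical order).
#' @export
setClass("HUVolume",
  representation(data = "array", spacing = "numeric", downAxis = "integer"),
  prototype(spacing = c(1, 1, 1), downAxis = 2L))

setValidity("HUVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (!all(is.finite(object@data))) msg <- c(msg, "all HU values must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (!object@downAxis %in% c(2L, 3L))
    msg <- c(msg, "downAxis must be an in-slice axis (2 or 3)")
  if (length(msg)) msg else TRUE
})

#' Construct an HUVolume
#' @param data 3-D numeric array of HU values.
#' @param spacing voxel spacing in mm, (slice, down, right).
#' @param downAxis in-slice axis pointing toward the table (default 2).
#' @return an \linkS4class{HUVolume}.
#' @export
HUVolume <- function(data, spacing = c(1, 1, 1), downAxis = 2L) {
  new("HUVolume", data = data, spacing = as.numeric(spacing),
      downAxis = as.integer(downAxis))
}

#' LabelMap: integer labels on the grid of a volume
#'
#' Non-negative integer labels sharing the shape of a source HUVolume;
#' label 0 is background. The legend maps labels to names.
#'
#' @slot data 3-D integer array.
#' @slot legend named character vector, names are label values.
#' @export
setClass("LabelMap",
  representation(data = "array", legend = "character"),
  prototype(legend = character()))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (any(object@data < 0)) msg <- c(msg, "labels must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#' @param data 3-D integer (or logical) array; logicals become 0/1.
#' @param legend named character vector mapping labels to names.
#' @return a \linkS4class{LabelMap}.
#' @export
LabelMap <- function(data, legend = character()) {
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  new("LabelMap", data = data, legend = legend)
}

#' TransitionModel: the arch model of a two-material transition
#'
#' Parameters of the partial-volume transition between two materials: the
#' low and high bases (mean attenuations of the pure materials), the
#' Gaussian scale along the gradient direction, and the noise-invariance
#' factor applied to the scaled first derivative.
#'
#' @slot pair transition name, one of "TA" (air-tagging), "TT"
#'   (tissue-tagging), "SA" (air-tissue).
#' @slot L low base (HU).
#' @slot H high base (HU).
#' @slot sigmaOmega Gaussian scale along the gradient direction (voxels).
#' @slot theta dimensionless scaling of the derivative axis.
#' @export
setClass("TransitionModel",
  representation(pair = "character", L = "numeric", H = "numeric",
                 sigmaOmega = "numeric", theta = "numeric"),
  prototype(pair = "TA", sigmaOmega = 1, theta = 1))

setValidity("TransitionModel", function(object) {
  msg <- character()
  if (!is.finite(object@L) || !is.finite(object@H) || object@L >= object@H)
    msg <- c(msg, "bases must satisfy L < H")
  if (object@sigmaOmega <= 0) msg <- c(msg, "sigmaOmega must be positive")
  if (object@theta <= 0) msg <- c(msg, "theta must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a TransitionModel
#' @param pair "TA", "TT" or "SA".
#' @param L,H low and high bases in HU (L < H).
#' @param sigmaOmega gradient-direction Gaussian scale in voxels.
#' @param theta noise-invariance factor.
#' @return a \linkS4class{TransitionModel}.
#' @export
TransitionModel <- function(pair, L, H, sigmaOmega = 1, theta = 1) {
  new("TransitionModel", pair = pair, L = as.numeric(L), H = as.numeric(H),
      sigmaOmega = as.numeric(sigmaOmega), theta = as.numeric(theta))
}

#' FractionField: per-voxel three-material fractions
#'
#' Per-voxel fractions of air, soft tissue and tagged material, each in
#' [0, 1] and summing to 1.
#'
#' @slot tAir,tST,tTR 3-D numeric arrays of identical shape.
#' @export
setClass("FractionField",
  representation(tAir = "array", tST = "array", tTR = "array"))

setValidity("FractionField", function(object) {
  msg <- character()
  if (!identical(dim(object@tAir), dim(object@tST)) ||
      !identical(dim(object@tAir), dim(object@tTR)))
    msg <- c(msg, "fraction arrays must share a shape")
  rng <- range(object@tAir, object@tST, object@tTR)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "fractions must lie in [0, 1]")
  s <- object@tAir + object@tST + object@tTR
  if (max(abs(s - 1)) > 1e-9) msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' LayerComponent: a labeled thin connected layer
#'
#' A connected component of thin-layer voxels with its class and the
#' directional connectivity counts to the adjacent tagged pool used for
#' the AT-versus-ATT decision.
#'
#' @slot id positive integer component id.
#' @slot voxels integer matrix, one row per voxel, columns (slice, down,
#'   right), 1-based.
#' @slot cls "ambiguous", "AT", "ATT" or "STT".
#' @slot adjacentFTM integer ids of adjacent tagged pools.
#' @slot connHorizontal,connVertical connectivity counts against the
#'   decisive pool.
#' @export
setClass("LayerComponent",
  representation(id = "integer", voxels = "matrix", cls = "character",
                 adjacentFTM = "integer", connHorizontal = "integer",
                 connVertical = "integer"),
  prototype(cls = "ambiguous", adjacentFTM = integer(),
            connHorizontal = 0L, connVertical = 0L))

setValidity("LayerComponent", function(object) {
  msg <- character()
  if (nrow(object@voxels) < 1L) msg <- c(msg, "component must be non-empty")
  if (!object@cls %in% c("ambiguous", "AT", "ATT", "STT"))
    msg <- c(msg, "unknown layer class")
  if (object@cls == "AT" && object@connHorizontal > object@connVertical)
    msg <- c(msg, "AT requires vertical >= horizontal connectivity")
  if (object@cls == "ATT" && object@connHorizontal <= object@connVertical)
    msg <- c(msg, "ATT requires horizontal > vertical connectivity")
  if (length(msg)) msg else TRUE
})

#' CleanseConfig: parameters of the cleansing pipeline
#'
#' All tunable constants of the pipeline: the per-material attenuation
#' thresholds, the leaping distance of the layer classifier, the lumen
#' dilation radius, Gaussian scales, and the Eq-style gates.
#'
#' @slot thresholds named numeric vector (see [defaultThresholds()]).
#' @slot leapDistance probe length in voxels for layer classification.
#' @slot dilationRadius lumen dilation ball radius in voxels.
#' @slot sigmaGDSD Gaussian scale of the second-derivative filter.
#' @slot sigmaOmega Gaussian scale for gradient sampling.
#' @slot sigmaWall wall-smoothing Gaussian scale.
#' @slot pehHuGate minimum HU for the tissue-side replacement rule.
#' @slot huWindow HU window mapped to [0,1] for the GDSD.
#' @slot gradEps gradient floor (normalized units) below which the GDSD is 0.
#' @slot connectivity region-growing connectivity (6 or 26).
#' @slot thetaMode "apex_match" or "fixed".
#' @slot projectionSamples curve-sampling density of the projection.
#' @export
setClass("CleanseConfig",
  representation(thresholds = "numeric", leapDistance = "integer",
                 dilationRadius = "numeric", sigmaGDSD = "numeric",
                 sigmaOmega = "numeric", sigmaWall = "numeric",
                 pehHuGate = "numeric", huWindow = "numeric",
                 gradEps = "numeric", connectivity = "integer",
                 thetaMode = "character", projectionSamples = "integer"))

setValidity("CleanseConfig", function(object) {
  msg <- character()
  if (object@leapDistance < 1L) msg <- c(msg, "leapDistance must be >= 1")
  if (object@dilationRadius < 0) msg <- c(msg, "dilationRadius must be >= 0")
  for (s in c("sigmaGDSD", "sigmaOmega", "sigmaWall"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (length(object@huWindow) != 2L || diff(object@huWindow) <= 0)
    msg <- c(msg, "huWindow must be an increasing pair")
  if (!object@connectivity %in% c(6L, 26L))
    msg <- c(msg, "connectivity must be 6 or 26")
  if (!object@thetaMode %in% c("apex_match", "fixed"))
    msg <- c(msg, "thetaMode must be 'apex_match' or 'fixed'")
  thr <- object@thresholds
  need <- names(defaultThresholds())
  if (!all(need %in% names(thr)))
    msg <- c(msg, paste("missing thresholds:",
                        paste(setdiff(need, names(thr)), collapse = ", ")))
  else {
    for (p in c("lumen_air", "soft_tissue", "ftm", "at_layer")) {
      if (thr[paste0(p, "_min")] >= thr[paste0(p, "_max")])
        msg <- c(msg, paste0("threshold range ", p, " must have min < max"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' QCReport: quality-control summary of a cleansing run
#'
#' @slot counts named numeric vector of voxel counts per stage.
#' @slot layers data.frame of layer components and their classes.
#' @slot bases data.frame of estimated transition-model parameters.
#' @slot warnings character vector of stage warnings.
#' @slot timings named numeric vector of per-stage elapsed seconds.
#' @export
setClass("QCReport",
  representation(counts = "numeric", layers = "data.frame",
                 bases = "data.frame", warnings = "character",
                 timings = "numeric"))

#' PhantomSpec: parametric description of a synthetic scene
#'
#' @slot shape integer length-3 grid shape (slice, down, right).
#' @slot spacing voxel spacing in mm.
#' @slot scene scene name (see [makeTestSuiteScenes()]).
#' @slot materials named numeric vector of material mean attenuations (HU).
#' @slot psfSigma Gaussian point-spread scale in voxels.
#' @slot noiseSigma additive Gaussian noise SD in HU.
#' @slot pehAmplitude pseudo-enhancement amplitude in HU.
#' @slot pehDecay pseudo-enhancement decay length in voxels.
#' @slot params named list of scene geometry parameters.
#' @slot seed RNG seed for the noise.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", scene = "character",
                 materials = "numeric", psfSigma = "numeric",
                 noiseSigma = "numeric", pehAmplitude = "numeric",
                 pehDecay = "numeric", params = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  m <- object@materials
  if (!all(c("air", "st", "ftm") %in% names(m)))
    msg <- c(msg, "materials must name air, st, ftm")
  else if (!(m["air"] < m["st"] && m["st"] < m["ftm"]))
    msg <- c(msg, "material means must be ordered air < st < ftm")
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth accompanying a phantom volume
#'
#' @slot materials \linkS4class{LabelMap} of dominant materials
#'   (1 air, 2 soft tissue, 3 tagged material, 4 bone).
#' @slot fractions \linkS4class{FractionField} of subvoxel fractions.
#' @slot atMask,attMask 3-D logical arrays of true AT / ATT layer voxels.
#' @slot features named list of logical feature masks (fold, polyp,
#'   surfaces, centerlines, pure tagged material, ...).
#' @slot peh 3-D numeric array of the added pseudo-enhancement (HU).
#' @export
setClass("PhantomTruth",
  representation(materials = "LabelMap", fractions = "FractionField",
                 atMask = "array", attMask = "array", features = "list",
                 peh = "array"))

# ---- accessors ----------------------------------------------------------

#' Accessors for volumetric containers
#'
#' `voxelData` returns the raw 3-D array of an HUVolume or LabelMap;
#' `spacing` and `downAxis` return grid metadata; `layerClass` and
#' `layerVoxels` access a LayerComponent.
#'
#' @param x an object.
#' @return the corresponding slot value.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname voxelData
#' @export
setMethod("voxelData", "HUVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelMap", function(x) x@data)

#' @rdname voxelData
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname voxelData
#' @export
setMethod("spacing", "HUVolume", function(x) x@spacing)

#' @rdname voxelData
#' @export
setGeneric("downAxis", function(x) standardGeneric("downAxis"))
#' @rdname voxelData
#' @export
setMethod("downAxis", "HUVolume", function(x) x@downAxis)

#' @rdname voxelData
#' @export
setGeneric("layerClass", function(x) standardGeneric("layerClass"))
#' @rdname voxelData
#' @export
setMethod("layerClass", "LayerComponent", function(x) x@cls)

#' @rdname voxelData
#' @export
setGeneric("layerVoxels", function(x) standardGeneric("layerVoxels"))
#' @rdname voxelData
#' @export
setMethod("layerVoxels", "LayerComponent", function(x) x@voxels)

# ---- show methods -------------------------------------------------------

setMethod("show", "HUVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("HUVolume %d x %d x %d (slice, down, right)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3f x %.3f x %.3f mm; down axis: %d\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@downAxis))
  cat(sprintf("  HU range: [%.1f, %.1f]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  k <- max(object@data)
  cat(sprintf("LabelMap %d x %d x %d, %d label(s)\n", d[1], d[2], d[3], k))
  if (length(object@legend))
    cat("  legend:", paste(names(object@legend), object@legend,
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel %s: L = %.1f HU, H = %.1f HU, sigma = %.2f, theta = %.3f\n",
              object@pair, object@L, object@H, object@sigmaOmega, object@theta))
})

setMethod("show", "LayerComponent", function(object) {
  cat(sprintf("LayerComponent #%d [%s]: %d voxel(s), conn H/V = %d/%d, pools: %s\n",
              object@id, object@cls, nrow(object@voxels),
              object@connHorizontal, object@connVertical,
              paste(object@adjacentFTM, collapse = ",")))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n  counts:\n")
  for (n in names(object@counts))
    cat(sprintf("    %-28s %s\n", n, format(object@counts[[n]])))
  if (nrow(object@layers)) {
    cat("  layers:\n")
    print(object@layers)
  }
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})
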