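# All pipeline constants live here; stage code takes them from a
# CleanseConfig rather than hard-coding numbers.

#' Standard attenuation thresholds
#'
#' The observed standard CT attenuation ranges of the materials of a
#' fecal-tagged colonography scan, plus the cut values used for lumen
#' detection: lumen air is identified below -600 HU and tagged material
#' above 200 HU; -100 HU is the soft-tissue floor used by the
#' region-growing removal steps.
#'
#' @return named numeric vector of thresholds in HU.
#' @export
defaultThresholds <- function() {
  c(lumen_air_min   = -1000, lumen_air_max = -800,
    soft_tissue_min = -100,  soft_tissue_max = 100,
    ftm_min         = 200,   ftm_max = 1400,
    at_layer_min    = -800,  at_layer_max = 600,
    lumen_air_cut   = -600,
    ftm_cut         = 200,
    st_floor        = -100)
}

#' Build a cleansing configuration
#'
#' Returns a \linkS4class{CleanseConfig} populated with the standard
#' constants: Table-range thresholds, lumen dilation radius 3 (the assumed
#' partial-volume layer thickness), leaping distance 5 for layer
#' classification, Gaussian scale 1 for the second-derivative filter, and
#' wall smoothing at scale 0.5. Any argument overrides its default.
#'
#' @param thresholds named numeric vector, see [defaultThresholds()].
#' @param leapDistance probe length (voxels) of the layer classifier.
#' @param dilationRadius lumen dilation ball radius (voxels).
#' @param sigmaGDSD scale of the gradient-directional second derivative.
#' @param sigmaOmega scale of the gradient used for edge samples.
#' @param sigmaWall wall-smoothing scale.
#' @param pehHuGate HU gate of the tissue-side replacement rule.
#' @param huWindow HU window normalized to [0, 1] for the GDSD.
#' @param gradEps gradient floor in normalized units.
#' @param connectivity region-growing connectivity (6 or 26).
#' @param thetaMode "apex_match" (calibrate theta per transition) or "fixed".
#' @param projectionSamples curve sampling density of the projection.
#' @return a \linkS4class{CleanseConfig}.
#' @export
cleanseConfig <- function(thresholds = defaultThresholds(),
                          leapDistance = 5L,
                          dilationRadius = 3,
                          sigmaGDSD = 1,
                          sigmaOmega = 1,
                          sigmaWall = 0.5,
                          pehHuGate = 100,
                          huWindow = c(-1000, 1400),
                          gradEps = 1e-4,
                          connectivity = 6L,
                          thetaMode = "apex_match",
                          projectionSamples = 1024L) {
  thr <- defaultThresholds()
  thr[names(thresholds)] <- thresholds
  new("CleanseConfig", thresholds = thr,
      leapDistance = as.integer(leapDistance),
      dilationRadius = as.numeric(dilationRadius),
      sigmaGDSD = as.numeric(sigmaGDSD),
      sigmaOmega = as.numeric(sigmaOmega),
      sigmaWall = as.numeric(sigmaWall),
      pehHuGate = as.numeric(pehHuGate),
      huWindow = as.numeric(huWindow),
      gradEps = as.numeric(gradEps),
      connectivity = as.integer(connectivity),
      thetaMode = thetaMode,
      projectionSamples = as.integer(projectionSamples))
}

.configKeys <- c("thresholds", "leap_distance", "dilation_radius",
                 "sigma_gdsd", "sigma_omega", "sigma_wall", "peh_hu_gate",
                 "hu_window", "grad_eps", "connectivity", "theta_mode",
                 "projection_samples")

#' Parse a configuration file
#'
#' Reads a YAML (or JSON) configuration and fills every unset key with the
#' standard defaults of [cleanseConfig()]. Unknown keys are rejected; an
#' empty file yields the full default configuration.
#'
#' @param path path to a YAML/JSON file.
#' @return a \linkS4class{CleanseConfig}.
#' @export
parseConfig <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  args <- list()
  if (!is.null(cfg$thresholds)) args$thresholds <- unlist(cfg$thresholds)
  map <- c(leap_distance = "leapDistance", dilation_radius = "dilationRadius",
           sigma_gdsd = "sigmaGDSD", sigma_omega = "sigmaOmega",
           sigma_wall = "sigmaWall", peh_hu_gate = "pehHuGate",
           hu_window = "huWindow", grad_eps = "gradEps",
           connectivity = "connectivity", theta_mode = "thetaMode",
           projection_samples = "projectionSamples")
  for (k in names(map)) if (!is.null(cfg[[k]])) args[[map[k]]] <- cfg[[k]]
  do.call(cleanseConfig, args)
}

#' Serialize a configuration to YAML
#'
#' The counterpart of [parseConfig()]; `parseConfig(dumpConfig(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a \linkS4class{CleanseConfig}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dumpConfig <- function(cfg, path) {
  out <- list(
    thresholds = as.list(cfg@thresholds),
    leap_distance = cfg@leapDistance,
    dilation_radius = cfg@dilationRadius,
    sigma_gdsd = cfg@sigmaGDSD,
    sigma_omega = cfg@sigmaOmega,
    sigma_wall = cfg@sigmaWall,
    peh_hu_gate = cfg@pehHuGate,
    hu_window = cfg@huWindow,
    grad_eps = cfg@gradEps,
    connectivity = cfg@connectivity,
    theta_mode = cfg@thetaMode,
    projection_samples = cfg@projectionSamples)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Serialize a QC report to JSON
#'
#' @param qc a \linkS4class{QCReport}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(qc, path) {
  out <- list(counts = as.list(qc@counts),
              layers = qc@layers,
              bases = qc@bases,
              warnings = qc@warnings,
              timings = as.list(qc@timings))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
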