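# One flat configuration object holding every numeric constant of the
# analysis, so the defaults are greppable and testable in one place.

#' Analysis configuration
#'
#' All tunable constants of the pipelines with their default values:
#' mask thresholds (ratio-image 2.0, normalized marker 1.4, boxcar width
#' 11 px, 7x7 Gaussian with sigma 200 nm, minimum nucleolus area 20 px),
#' FCS fit bounds (diffusion time >= 200 µs, dark-state relaxation
#' <= 150 µs) and calibration (0.14 ms, 90 µm²/s, structure parameter 8),
#' and FRAP constants (0.331 s/frame, 207 nm pixels, 6 px bleach radius,
#' 207 nm ring pitch, 30 pre-bleach of 210 frames). Any override is
#' reported via a message.
#'
#' @param ... named overrides of the defaults.
#' @param quiet suppress the override messages.
#' @return a named list with class `"subnucqConfig"`.
#' @examples
#' cfg <- analysisConfig(markerThreshold = 1.5)
#' cfg$ratioThreshold
#' @export
analysisConfig <- function(..., quiet = FALSE) {
  defaults <- list(
    # imaging / masks
    pixelSizeNm = 207,
    ratioThreshold = 2.0,
    markerThreshold = 1.4,
    boxcarWidth = 11L,
    gaussianSize = 7L,
    gaussianSigmaNm = 200,
    minNucleolusArea = 20L,
    partialVolumeGuardPx = 2L,
    minBackgroundArea = 50L,
    modeBinFraction = 0.01,
    # FCS
    tauDifLowerS = 200e-6,
    tauTripUpperS = 150e-6,
    calTauRefS = 0.14e-3,
    calDRef = 90,
    calStructureParameter = 8,
    segmentTolerance = 0.2,
    # FRAP
    frameIntervalS = 0.331,
    bleachRadiusPx = 6,
    ringPitchNm = 207,
    preBleachFrames = 30L,
    totalFrames = 210L,
    # reproducibility
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  if (!quiet) for (nm in names(overrides))
    message("config override: ", nm, " = ", format(overrides[[nm]]),
            " (default ", format(defaults[[nm]]), ")")
  structure(cfg, class = c("subnucqConfig", "list"))
}

#' Read an analysis configuration from a YAML file
#'
#' Unspecified fields keep their defaults; specified fields are reported as
#' overrides.
#'
#' @param path YAML file with a flat mapping of config fields.
#' @param quiet suppress override messages.
#' @export
readConfig <- function(path, quiet = FALSE) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(analysisConfig, c(vals, list(quiet = quiet)))
}

#' Write an analysis configuration to YAML
#' @param config an [analysisConfig()].
#' @param path output file.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' FCS calibration from a config
#' @param config an [analysisConfig()].
#' @export
calibrationFromConfig <- function(config = analysisConfig()) {
  FCSCalibration(tauRef = config$calTauRefS, DRef = config$calDRef,
                 a = config$calStructureParameter)
}
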