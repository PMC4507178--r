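#' @include AllClasses.R
NULL

#' Construct a MultiChannelImage
#'
#' @param channels named list of numeric matrices (typical names: `marker`,
#'   `reference`, `construct`).
#' @param pixelSize pixel size in nm.
#' @param bitDepth nominal bit depth.
#' @return a [MultiChannelImage-class] object.
#' @export
MultiChannelImage <- function(channels, pixelSize = 207, bitDepth = 16) {
  channels <- lapply(channels, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  new("MultiChannelImage", channels = channels,
      pixelSize = as.numeric(pixelSize), bitDepth = as.numeric(bitDepth))
}

#' Extract one channel of a MultiChannelImage
#' @param x a MultiChannelImage.
#' @param name channel name.
#' @return numeric matrix.
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname channel
#' @export
setMethod("channel", "MultiChannelImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
})

#' Channel names of a MultiChannelImage
#' @param x a MultiChannelImage.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) names(x@channels))

#' Physical pixel size in nm
#' @param x an object with a pixel size.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSize)

#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@channels[[1]]))

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat("MultiChannelImage:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s) [",
      paste(names(object@channels), collapse = ", "), "]\n")
  cat("  pixel size:", object@pixelSize, "nm; bit depth:",
      object@bitDepth, "\n")
})

#' Accessor for masks in a MaskSet
#'
#' @param x a [MaskSet-class].
#' @param which one of `"background"`, `"cytoplasm"`, `"nucleus"`,
#'   `"nucleolarInitial"`, `"nucleolarFinal"`, `"nucleolarLabels"`,
#'   `"nucleoplasm"`.
#' @return logical matrix (integer matrix for `"nucleolarLabels"`).
#' @export
setGeneric("maskLayer", function(x, which) standardGeneric("maskLayer"))

#' @rdname maskLayer
#' @export
setMethod("maskLayer", "MaskSet", function(x, which) {
  slot(x, match.arg(which, c("background", "cytoplasm", "nucleus",
                             "nucleolarInitial", "nucleolarFinal",
                             "nucleolarLabels", "nucleoplasm")))
})

#' Threshold provenance of a MaskSet
#' @param x a MaskSet.
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))

#' @rdname maskProvenance
#' @export
setMethod("maskProvenance", "MaskSet", function(x) x@provenance)

setMethod("show", "MaskSet", function(object) {
  nNu <- length(setdiff(unique(as.vector(object@nucleolarLabels)), 0L))
  cat("MaskSet:", nrow(object@nucleus), "x", ncol(object@nucleus), "px\n")
  cat("  nucleus:", sum(object@nucleus), "px; nucleoplasm:",
      sum(object@nucleoplasm), "px; refined nucleoli:", nNu, "\n")
})

setMethod("show", "RatioSummary", function(object) {
  cat("RatioSummary over", nrow(object@cells), "cell(s),",
      nrow(object@nucleoli), "nucleoli\n")
  for (nm in names(object@population)) {
    p <- object@population[[nm]]
    if (p$ciDefined)
      cat(sprintf("  %-12s %.3f  [%.3f, %.3f]  (n = %d)\n", nm,
                  p$mean, p$ciLow, p$ciHigh, p$n))
    else
      cat(sprintf("  %-12s %.3f  (n = %d; CI undefined)\n", nm, p$mean, p$n))
  }
})

#' Per-cell ratio table of a RatioSummary
#' @param x a RatioSummary.
#' @export
setGeneric("cellRatios", function(x) standardGeneric("cellRatios"))

#' @rdname cellRatios
#' @export
setMethod("cellRatios", "RatioSummary", function(x) x@cells)

#' Per-nucleolus ratio table of a RatioSummary
#' @param x a RatioSummary.
#' @export
setGeneric("nucleolusRatios", function(x) standardGeneric("nucleolusRatios"))

#' @rdname nucleolusRatios
#' @export
setMethod("nucleolusRatios", "RatioSummary", function(x) x@nucleoli)

#' Population summaries of a RatioSummary
#' @param x a RatioSummary.
#' @export
setGeneric("populationStats", function(x) standardGeneric("populationStats"))

#' @rdname populationStats
#' @export
setMethod("populationStats", "RatioSummary", function(x) x@population)

#' @export
setMethod("coef", "FCSFit", function(object, ...) object@params)

#' Flags for parameters lying on a fit bound
#' @param x a fit object.
#' @export
setGeneric("atBound", function(x) standardGeneric("atBound"))

#' @rdname atBound
#' @export
setMethod("atBound", "FCSFit", function(x) x@atBound)

setMethod("show", "FCSFit", function(object) {
  p <- object@params
  cat("FCSFit (one-component 3-D diffusion + dark state)\n")
  cat(sprintf("  N = %.3f, T = %.3f, tauTrip = %.1f us, tauDif = %.4g ms, a = %.3f\n",
              p[["N"]], p[["T"]], p[["tauTrip"]] * 1e6, p[["tauDif"]] * 1e3,
              p[["a"]]))
  if (any(object@atBound))
    cat("  at bound:", paste(names(object@atBound)[object@atBound],
                             collapse = ", "), "\n")
  if (any(object@fixed))
    cat("  fixed:", paste(names(object@fixed)[object@fixed],
                          collapse = ", "), "\n")
})

#' Construct an FCS calibration
#'
#' Defaults are the free-fluorophore buffer calibration: diffusion time
#' 0.14 ms, diffusion coefficient 90 µm²/s, structure parameter 8.
#'
#' @param tauRef reference diffusion time (s).
#' @param DRef reference diffusion coefficient (µm²/s).
#' @param a volume structure parameter.
#' @export
FCSCalibration <- function(tauRef = 0.14e-3, DRef = 90, a = 8) {
  new("FCSCalibration", tauRef = tauRef, DRef = DRef, a = a)
}

setMethod("show", "FCSCalibration", function(object) {
  cat(sprintf("FCSCalibration: tauRef = %.3g ms, DRef = %g um^2/s, a = %g\n",
              object@tauRef * 1e3, object@DRef, object@a))
})

#' Construct a FRAPTraces object
#'
#' @param time frame times (s), uniformly spaced.
#' @param roi bleached-region mean fluorescence per frame.
#' @param compartment nucleus / whole-cell mean fluorescence per frame.
#' @param background background fluorescence (scalar or per frame).
#' @param bleachFrame index of the first post-bleach frame.
#' @param preBleachFrames number of pre-bleach frames.
#' @export
FRAPTraces <- function(time, roi, compartment, background = 0,
                       bleachFrame = 31L, preBleachFrames = 30L) {
  new("FRAPTraces", time = as.numeric(time), roi = as.numeric(roi),
      compartment = as.numeric(compartment),
      background = as.numeric(background),
      bleachFrame = as.integer(bleachFrame),
      preBleachFrames = as.integer(preBleachFrames))
}

setMethod("show", "FRAPTraces", function(object) {
  cat("FRAPTraces:", length(object@time), "frames,",
      object@preBleachFrames, "pre-bleach, bleach at frame",
      object@bleachFrame, "\n")
  cat(sprintf("  frame interval: %.3f s\n", diff(object@time[1:2])))
})

setMethod("show", "ScanBleachFit", function(object) {
  cat(sprintf(
    "ScanBleachFit: A0 = %.3f, A1 = %.3f (tauA = %.3g s), A2 = %.3f (tauB = %.3g s)\n",
    object@A0, object@A1, object@tauA, object@A2, object@tauB))
  cat(sprintf("  step loss s = %.4f%s\n", object@step,
              if (object@singleExp) " [single-exponential fallback]" else ""))
})

setMethod("show", "RecoveryFit", function(object) {
  cat(sprintf(
    "RecoveryFit: a1 = %.3f, tau1 = %.3f s, a2 = %.3f, tau2 = %.3f s\n",
    object@a1, object@tau1, object@a2, object@tau2))
  cat(sprintf("  immobile fraction = %.3f%s\n", object@immobileFraction,
              if (object@singleExp) " [single-exponential fallback]" else ""))
})

#' @export
setMethod("coef", "RecoveryFit", function(object, ...) {
  c(a1 = object@a1, tau1 = object@tau1, a2 = object@a2, tau2 = object@tau2)
})

#' @export
setMethod("coef", "ScanBleachFit", function(object, ...) {
  c(A0 = object@A0, A1 = object@A1, tauA = object@tauA,
    A2 = object@A2, tauB = object@tauB, step = object@step)
})

setMethod("show", "RadialProfile", function(object) {
  cat("RadialProfile:", length(object@radius), "rings, pitch",
      object@pitch, "nm\n")
})

#' Coerce a RadialProfile to a data.frame
#' @param x a RadialProfile.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "RadialProfile", function(x, ...) {
  data.frame(radius_nm = x@radius, mean = x@mean, n = x@n)
})
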