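#' @import methods
NULL

#' Multi-channel confocal image
#'
#' A stack of co-registered 2-D intensity arrays with a physical pixel size.
#' Channel roles follow the three-colour localization assay: a nucleolar
#' marker (e.g. fibrillarin), a free-diffusing reference fluorophore
#' (e.g. mCherry) reporting accessible volume, and the construct of interest.
#'
#' @slot channels named list of numeric matrices, all the same dimension.
#' @slot pixelSize physical pixel size in nanometres.
#' @slot bitDepth nominal acquisition bit depth (metadata only; intensities
#'   are stored as floating point).
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
  representation(channels = "list", pixelSize = "numeric",
                 bitDepth = "numeric"),
  prototype(channels = list(), pixelSize = 207, bitDepth = 16))

setValidity("MultiChannelImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("no channels")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("channels must be matrices")
  d <- dim(ch[[1]])
  if (!all(vapply(ch, function(m) identical(dim(m), d), logical(1))))
    return("all channels must share the same dimensions")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number (nm)")
  TRUE
})

#' Mask set of the nucleolar segmentation pipeline
#'
#' Logical masks produced (or provided as ground truth) for one cell, with
#' the provenance of each threshold step. `nucleolarLabels` is an integer
#' matrix labelling the refined per-nucleolus masks (0 = background).
#'
#' @slot background logical matrix; cell-free region used for background
#'   estimation.
#' @slot cytoplasm logical matrix.
#' @slot nucleus logical matrix.
#' @slot nucleolarInitial logical matrix; ratio-image threshold result.
#' @slot nucleolarFinal logical matrix; normalized-marker threshold result.
#' @slot nucleolarLabels integer matrix; refined per-nucleolus masks.
#' @slot nucleoplasm logical matrix; nucleus minus final nucleolar mask.
#' @slot provenance list recording thresholds and levels used at each step.
#' @exportClass MaskSet
setClass("MaskSet",
  representation(background = "matrix", cytoplasm = "matrix",
                 nucleus = "matrix", nucleolarInitial = "matrix",
                 nucleolarFinal = "matrix", nucleolarLabels = "matrix",
                 nucleoplasm = "matrix", provenance = "list"))

setValidity("MaskSet", function(object) {
  refined <- object@nucleolarLabels > 0
  if (any(refined & !object@nucleolarFinal))
    return("refined nucleolar masks must be contained in the final mask")
  if (any(object@nucleolarFinal & !object@nucleus))
    return("final nucleolar mask must be contained in the nucleus")
  if (!identical(unname(object@nucleoplasm),
                 unname(object@nucleus & !object@nucleolarFinal)))
    return("nucleoplasm must equal nucleus minus final nucleolar mask")
  TRUE
})

#' Per-cell and population enrichment-ratio summary
#'
#' @slot cells data.frame with one row per cell: raw and reference-normalized
#'   cytoplasm/nucleoplasm ratios, per-cell raw (area-weighted) and adjusted
#'   nucleolus/nucleoplasm ratios, and the raw least-squares slope.
#' @slot nucleoli data.frame with one row per nucleolus (cell, label, area,
#'   raw ratio).
#' @slot population list of population summaries (mean, 95% CI, n) per
#'   quantity.
#' @exportClass RatioSummary
setClass("RatioSummary",
  representation(cells = "data.frame", nucleoli = "data.frame",
                 population = "list"))

#' FCS autocorrelation fit result
#'
#' Parameters of the one-component 3-D diffusion model with dark-state
#' (triplet/blinking) correction.
#'
#' @slot params named numeric: `N` (molecules in the detection volume),
#'   `T` (dark-state fraction), `tauTrip` (dark-state relaxation time, s),
#'   `tauDif` (diffusion time, s), `a` (volume structure parameter).
#' @slot se approximate standard errors (NA where unavailable).
#' @slot atBound named logical; TRUE where a parameter sits at a fit bound.
#' @slot residualNorm residual sum of squares of the (weighted) fit.
#' @slot fixed named logical; TRUE for parameters held fixed.
#' @exportClass FCSFit
setClass("FCSFit",
  representation(params = "numeric", se = "numeric", atBound = "logical",
                 residualNorm = "numeric", fixed = "logical"))

setValidity("FCSFit", function(object) {
  p <- object@params
  need <- c("N", "T", "tauTrip", "tauDif", "a")
  if (!all(need %in% names(p))) return("params must contain N, T, tauTrip, tauDif, a")
  if (p[["T"]] < 0 || p[["T"]] >= 1) return("dark-state fraction T must be in [0, 1)")
  if (p[["tauDif"]] <= 0 || p[["a"]] <= 0) return("tauDif and a must be positive")
  TRUE
})

#' FCS calibration
#'
#' Reference measurement of a freely diffusing fluorescent protein in buffer,
#' used to convert diffusion times to apparent diffusion coefficients and to
#' fix the detection-volume geometry.
#'
#' @slot tauRef reference diffusion time in seconds (default 0.14 ms).
#' @slot DRef reference diffusion coefficient in µm²/s (default 90).
#' @slot a volume structure parameter (default 8).
#' @exportClass FCSCalibration
setClass("FCSCalibration",
  representation(tauRef = "numeric", DRef = "numeric", a = "numeric"),
  prototype(tauRef = 0.14e-3, DRef = 90, a = 8))

setValidity("FCSCalibration", function(object) {
  if (object@tauRef <= 0 || object@DRef <= 0 || object@a <= 0)
    return("tauRef, DRef and a must be positive")
  TRUE
})

#' FRAP trace set
#'
#' Frame-resolved mean fluorescence of the bleached region of interest, the
#' enclosing compartment (nucleus or whole cell) and a background region.
#'
#' @slot time frame times in seconds (uniform spacing).
#' @slot roi mean fluorescence of the bleached circular region.
#' @slot compartment mean fluorescence of the nucleus / whole cell.
#' @slot background mean background fluorescence per frame.
#' @slot bleachFrame index of the first post-bleach frame.
#' @slot preBleachFrames number of pre-bleach frames.
#' @exportClass FRAPTraces
setClass("FRAPTraces",
  representation(time = "numeric", roi = "numeric", compartment = "numeric",
                 background = "numeric", bleachFrame = "integer",
                 preBleachFrames = "integer"))

setValidity("FRAPTraces", function(object) {
  n <- length(object@time)
  if (length(object@roi) != n || length(object@compartment) != n)
    return("time, roi and compartment must have equal length")
  if (length(object@background) != n && length(object@background) != 1L)
    return("background must have length 1 or length(time)")
  if (object@bleachFrame <= object@preBleachFrames)
    return("pre-bleach frames must precede the bleach frame")
  dt <- diff(object@time)
  if (n > 2L && max(abs(dt - dt[1])) > 1e-6 * dt[1])
    return("frame times must be uniformly spaced")
  TRUE
})

#' Scan-bleaching fit (double exponential with a step)
#'
#' @slot A0 offset of the double-exponential decay.
#' @slot A1,tauA fast decay amplitude and time constant (s).
#' @slot A2,tauB slow decay amplitude and time constant (s).
#' @slot step fractional fluorescence loss of the confined compartment at
#'   the bleach (the FLIP step), in [0, 1).
#' @slot singleExp TRUE when the double-exponential fit failed and a
#'   single-exponential fallback was used.
#' @exportClass ScanBleachFit
setClass("ScanBleachFit",
  representation(A0 = "numeric", A1 = "numeric", tauA = "numeric",
                 A2 = "numeric", tauB = "numeric", step = "numeric",
                 singleExp = "logical"),
  prototype(singleExp = FALSE))

setValidity("ScanBleachFit", function(object) {
  if (object@step < 0 || object@step >= 1) return("step must be in [0, 1)")
  if (object@tauA <= 0 || object@tauB <= 0) return("time constants must be positive")
  TRUE
})

#' Double-exponential FRAP recovery fit
#'
#' Fit of `1 - a1*exp(-t/tau1) - a2*exp(-t/tau2)` to the residual recovery
#' trace, with `tau1 <= tau2` by relabelling.
#'
#' @slot a1,tau1 fast component amplitude and time constant (s).
#' @slot a2,tau2 slow component amplitude and time constant (s).
#' @slot immobileFraction 1 minus the observed recovered plateau (tail mean
#'   of the residual trace).
#' @slot singleExp TRUE when the fit fell back to a single exponential.
#' @exportClass RecoveryFit
setClass("RecoveryFit",
  representation(a1 = "numeric", tau1 = "numeric", a2 = "numeric",
                 tau2 = "numeric", immobileFraction = "numeric",
                 singleExp = "logical"),
  prototype(singleExp = FALSE))

setValidity("RecoveryFit", function(object) {
  if (object@a1 < 0 || object@a2 < 0) return("amplitudes must be non-negative")
  if (object@tau1 > object@tau2) return("tau1 must not exceed tau2")
  TRUE
})

#' Radial bleach-spot profile
#'
#' Mean fluorescence in concentric rings around the bleach centre, one ring
#' per pixel pitch (207 nm by default); pixels outside the compartment mask
#' are omitted.
#'
#' @slot radius ring mid-radii in nm.
#' @slot mean mean fluorescence per ring (NA where a ring has no in-mask
#'   pixels).
#' @slot n pixel count per ring.
#' @slot pitch ring thickness in nm.
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(radius = "numeric", mean = "numeric", n = "integer",
                 pitch = "numeric"))
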