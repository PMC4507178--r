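# Synthetic FCS inputs: analytic autocorrelation curves with multiplicative
# noise, and Brownian-dynamics photon-count traces through a 3-D Gaussian
# detection volume.

#' Specify an FCS simulation
#'
#' @param mode `"analytic-noise"` (model curve times `1 + eps`) or
#'   `"brownian-trace"` (photon-count trace from diffusing point emitters).
#' @param params true model parameters: list or preset name (see
#'   [presetTable()]`("fcs")`); fields `N`, `T`, `tauTrip`, `tauDif` (s), `a`.
#' @param lagRange lag range in seconds for the analytic curve.
#' @param nLags number of log-spaced lags.
#' @param noiseSdRel relative sd of the multiplicative curve noise.
#' @param duration trace duration (s), brownian mode.
#' @param binWidth trace bin width (s), brownian mode.
#' @param brightness counts per second per molecule, brownian mode.
#' @param beamWaist lateral 1/e^2 radius of the detection volume (µm),
#'   brownian mode; together with `tauDif` it fixes D = w^2 / (4 tauDif).
#' @param seed integer seed.
#' @export
fcsSimSpec <- function(mode = c("analytic-noise", "brownian-trace"),
                       params = "calibration",
                       lagRange = c(1e-6, 1), nLags = 50L,
                       noiseSdRel = 0.02, duration = 10, binWidth = 1e-4,
                       brightness = 3e4, beamWaist = 0.25, seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(params)) params <- presetTable("fcs", params)
  stopifnot(params$tauDif > 0, params$T >= 0, params$T < 1, params$a > 0,
            params$N > 0, lagRange[1] > 0, diff(lagRange) > 0)
  list(mode = mode, params = params, lagRange = lagRange,
       nLags = as.integer(nLags), noiseSdRel = noiseSdRel,
       duration = duration, binWidth = binWidth, brightness = brightness,
       beamWaist = beamWaist, seed = as.integer(seed))
}

#' Simulate an FCS input with known truth
#'
#' In `analytic-noise` mode returns a log-spaced autocorrelation curve
#' `G(tau) = model(truth) * (1 + eps)`, `eps ~ N(0, noiseSdRel)`. In
#' `brownian-trace` mode simulates point emitters diffusing in a periodic
#' box, collects Poisson photon counts through a 3-D Gaussian detection
#' profile, and returns the binned trace.
#'
#' @param spec an [fcsSimSpec()].
#' @return list with `truth` (the generating parameters) and either
#'   `curve` (data.frame `lag`, `G`, `sd`) or `trace` (data.frame `time`,
#'   `counts`, plus `binWidth`).
#' @export
makeACF <- function(spec) {
  set.seed(spec$seed)
  if (spec$mode == "analytic-noise") {
    lag <- exp(seq(log(spec$lagRange[1]), log(spec$lagRange[2]),
                   length.out = spec$nLags))
    if (any(lag <= 0)) stop("lags must be positive")
    g0 <- modelACF(lag, spec$params)
    g <- g0 * (1 + stats::rnorm(length(lag), 0, spec$noiseSdRel))
    return(list(curve = data.frame(lag = lag, G = g,
                                   sd = abs(g0) * spec$noiseSdRel),
                truth = spec$params))
  }
  # brownian-trace mode
  p <- spec$params
  w <- spec$beamWaist                 # um, lateral
  wz <- p$a * w                       # um, axial
  D <- w^2 / (4 * p$tauDif)           # um^2/s
  # periodic box large enough that the detection profile is negligible at
  # its faces; molecule count set to match the target mean occupancy N
  box <- c(10 * w, 10 * w, 5 * wz)
  vEff <- pi^1.5 * w^2 * wz
  nMol <- max(1L, round(p$N * prod(box) / vEff))
  nBins <- as.integer(ceiling(spec$duration / spec$binWidth))
  sdStep <- sqrt(2 * D * spec$binWidth)
  center <- box / 2
  intensity <- numeric(nBins)
  for (m in seq_len(nMol)) {          # vectorized over time per molecule
    x <- (stats::runif(1, 0, box[1]) +
            cumsum(stats::rnorm(nBins, 0, sdStep))) %% box[1]
    y <- (stats::runif(1, 0, box[2]) +
            cumsum(stats::rnorm(nBins, 0, sdStep))) %% box[2]
    z <- (stats::runif(1, 0, box[3]) +
            cumsum(stats::rnorm(nBins, 0, sdStep))) %% box[3]
    intensity <- intensity +
      exp(-2 * ((x - center[1])^2 + (y - center[2])^2) / w^2 -
            2 * (z - center[3])^2 / wz^2)
  }
  counts <- stats::rpois(nBins, spec$brightness * spec$binWidth * intensity)
  list(trace = data.frame(time = (seq_len(nBins) - 0.5) * spec$binWidth,
                          counts = counts),
       binWidth = spec$binWidth, truth = p)
}
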