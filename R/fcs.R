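# FCS analysis: multiple-tau autocorrelation of binned photon traces,
# the one-component 3-D diffusion + dark-state model, bounded fitting,
# calibration conversion to apparent diffusion coefficients, and
# concentration estimation.

#' One-component 3-D diffusion autocorrelation model with dark-state term
#'
#' \deqn{G(\tau) = \frac{1}{N}\left[1 + \frac{T}{1-T} e^{-\tau/\tau_{Trip}}\right]
#'   \left(1 + \frac{\tau}{\tau_{Dif}}\right)^{-1}
#'   \left(1 + \frac{\tau}{a^2 \tau_{Dif}}\right)^{-1/2}}
#'
#' where `N` is the mean number of molecules in the detection volume, `T`
#' the dark-state (triplet/blinking) fraction, `tauTrip` its relaxation
#' time, `tauDif` the diffusion time and `a` the axial/lateral structure
#' parameter of the 3-D Gaussian volume.
#'
#' @param lag lag times in seconds (> 0).
#' @param params named list/vector with `N`, `T`, `tauTrip`, `tauDif`, `a`.
#' @return G values.
#' @examples
#' modelACF(1e-3, list(N = 1, T = 0, tauTrip = 1e-5, tauDif = 1e-3, a = 8))
#' @export
modelACF <- function(lag, params) {
  p <- as.list(params)
  if (any(lag <= 0)) stop("lags must be positive")
  if (p$T >= 1) stop("dark-state fraction T must be < 1")
  trip <- if (p$T > 0) 1 + p$T / (1 - p$T) * exp(-lag / p$tauTrip) else 1
  (1 / p$N) * trip * (1 + lag / p$tauDif)^-1 *
    (1 + lag / (p$a^2 * p$tauDif))^-0.5
}

#' Multiple-tau autocorrelation of a binned photon-count trace
#'
#' Computes the normalized fluctuation autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` on a quasi-logarithmic lag grid
#' (`m` lags per octave, trace binned 2x between octaves). Section quality
#' control: the trace is split into `nSegments` segments, segments whose
#' mean deviates more than `segmentTolerance` from the trace median (of
#' segment means) are dropped — the operational form of excluding stretches
#' with photobleaching or aggregation spikes — and the per-segment curves
#' are averaged.
#'
#' @param counts photon counts per bin (or a list as returned by
#'   [makeACF()] in `brownian-trace` mode).
#' @param binWidth bin width in seconds.
#' @param m lags per octave of the multiple-tau scheme.
#' @param nSegments number of QC segments.
#' @param segmentTolerance relative deviation above which a segment is
#'   dropped.
#' @param minBins minimum trace length in bins.
#' @return data.frame with `lag`, `G` and `sd` (between-segment standard
#'   error; NA with a single segment).
#' @export
autocorrelate <- function(counts, binWidth, m = 16L, nSegments = 10L,
                          segmentTolerance = 0.2, minBins = 1e4) {
  if (is.list(counts) && !is.null(counts$trace)) {
    binWidth <- counts$binWidth
    counts <- counts$trace$counts
  }
  counts <- as.numeric(counts)
  if (length(counts) < minBins)
    stop("trace has ", length(counts), " bins; need at least ", minBins)
  segLen <- floor(length(counts) / nSegments)
  segs <- lapply(seq_len(nSegments), function(i)
    counts[((i - 1) * segLen + 1):(i * segLen)])
  mu <- vapply(segs, mean, numeric(1))
  keep <- abs(mu - stats::median(mu)) <= segmentTolerance * stats::median(mu)
  if (!any(keep)) stop("all segments rejected by the quality control")
  curves <- lapply(segs[keep], .multipleTau, binWidth = binWidth, m = m)
  lag <- curves[[1]]$lag
  G <- rowMeans(do.call(cbind, lapply(curves, `[[`, "G")))
  sd <- if (length(curves) > 1L)
    apply(do.call(cbind, lapply(curves, `[[`, "G")), 1L, stats::sd) /
      sqrt(length(curves))
  else rep(NA_real_, length(lag))
  data.frame(lag = lag, G = G, sd = sd)
}

# Multiple-tau estimator on one segment. Classic scheme: m linear lags per
# level, then bin the trace by 2 and continue with lags m/2+1 ... m.
.multipleTau <- function(x, binWidth, m = 16L) {
  mean0 <- mean(x)
  if (mean0 == 0) stop("empty trace (zero mean)")
  lags <- numeric(0); G <- numeric(0)
  level <- 0L
  dt <- binWidth
  repeat {
    n <- length(x)
    lagIdx <- if (level == 0L) seq_len(m) else (m %/% 2L + 1L):m
    if (n < 2L * max(lagIdx)) break
    mx <- mean(x)
    for (k in lagIdx) {
      a <- x[1:(n - k)]; b <- x[(k + 1):n]
      G <- c(G, mean(a * b) / (mean(a) * mean(b)) - 1)
      lags <- c(lags, k * dt)
    }
    # bin by two for the next octave
    if (n %/% 2L < 2L * m) break
    x <- (x[seq(1L, 2L * (n %/% 2L), by = 2L)] +
            x[seq(2L, 2L * (n %/% 2L), by = 2L)]) / 2
    dt <- dt * 2
    level <- level + 1L
  }
  data.frame(lag = lags, G = G)
}

#' Fit the autocorrelation model to a curve
#'
#' Bounded weighted least squares (Levenberg–Marquardt). Default bounds
#' follow the reported fitting constraints for cellular data: the diffusion
#' time is bounded below at 200 µs and the dark-state relaxation time above
#' at 150 µs. For calibration data (free fluorophore in buffer, whose
#' diffusion time lies below the cellular bound) pass `tauDifLower = 0`;
#' the structure parameter is then typically left free, while for cellular
#' data it is fixed to the calibration value via `fixA`.
#'
#' @param curve data.frame with `lag`, `G` and optionally `sd` (per-lag
#'   noise; used for inverse-variance weights when finite).
#' @param fixA fix the structure parameter at this value (NULL = free).
#' @param tauDifLower lower bound on the diffusion time (s).
#' @param tauTripUpper upper bound on the dark-state relaxation time (s).
#' @param start optional named list of start values.
#' @param boundTolerance relative closeness at which a parameter is flagged
#'   as sitting on a bound.
#' @return an [FCSFit-class].
#' @export
fitACF <- function(curve, fixA = NULL, tauDifLower = 200e-6,
                   tauTripUpper = 150e-6, start = NULL,
                   boundTolerance = 1e-3) {
  stopifnot(all(c("lag", "G") %in% names(curve)))
  curve <- curve[is.finite(curve$G) & curve$lag > 0, ]
  if (nrow(curve) < 20L) stop("need at least 20 lag points")
  if (log10(max(curve$lag) / min(curve$lag)) < 3)
    stop("lag grid must span at least 3 decades")
  lag <- curve$lag; G <- curve$G
  w <- if (!is.null(curve$sd) && all(is.finite(curve$sd)) &&
           all(curve$sd > 0)) 1 / curve$sd^2 else rep(1, length(lag))

  if (is.null(start)) {
    G0 <- max(mean(G[seq_len(3L)]), 1e-6)
    tauHalf <- lag[which.min(abs(G - G0 / 2))]
    # keep the dark-state start inside the resolvable lag range so its
    # Jacobian column is non-degenerate on coarse grids
    tauTripStart <- min(tauTripUpper / 2, max(2e-5, min(lag) / 2))
    start <- list(N = 1 / G0, T = 0.1, tauTrip = tauTripStart,
                  tauDif = max(tauHalf, tauDifLower * 1.001, min(lag)))
    if (is.null(fixA)) start$a <- 8
  } else if (is.null(fixA) && is.null(start$a)) start$a <- 8

  lower <- c(N = 1e-6, T = 0, tauTrip = 1e-7,
             tauDif = max(tauDifLower, 1e-7))
  upper <- c(N = Inf, T = 0.9999, tauTrip = tauTripUpper, tauDif = Inf)
  if (is.null(fixA)) { lower <- c(lower, a = 0.5); upper <- c(upper, a = 100) }

  resid <- function(p) {
    pl <- as.list(p)
    if (!is.null(fixA)) pl$a <- fixA
    sqrt(w) * (G - modelACF(lag, pl))
  }
  fit <- .lmFit(unlist(start[names(lower)]), lower, upper, resid)
  if (!fit$converged)
    stop("ACF fit did not converge: ", fit$message, call. = FALSE)
  est <- fit$par
  se <- fit$se
  params <- c(N = unname(est[["N"]]), T = unname(est[["T"]]),
              tauTrip = unname(est[["tauTrip"]]),
              tauDif = unname(est[["tauDif"]]),
              a = if (is.null(fixA)) unname(est[["a"]]) else fixA)
  rel <- function(x, b) is.finite(b) && abs(x - b) <= boundTolerance * max(abs(b), 1e-12)
  atB <- c(N = FALSE, T = rel(params[["T"]], 0),
           tauTrip = rel(params[["tauTrip"]], tauTripUpper),
           tauDif = rel(params[["tauDif"]], lower[["tauDif"]]),
           a = if (is.null(fixA)) rel(params[["a"]], 0.5) else FALSE)
  seFull <- c(se[c("N", "T", "tauTrip", "tauDif")],
              if (is.null(fixA)) se[["a"]] else NA_real_)
  names(seFull) <- names(params)
  new("FCSFit", params = params, se = seFull, atBound = atB,
      residualNorm = fit$deviance,
      fixed = c(N = FALSE, T = FALSE, tauTrip = FALSE, tauDif = FALSE,
                a = !is.null(fixA)))
}

#' Convert a diffusion time to an apparent diffusion coefficient
#'
#' Under a shared detection volume, `D = DRef * tauRef / tauDif`, with the
#' reference pair from the buffer calibration (defaults: 0.14 ms, 90
#' µm²/s).
#'
#' @param tauDif diffusion time in seconds (vectorized).
#' @param calibration an [FCSCalibration()].
#' @return apparent diffusion coefficient(s) in µm²/s.
#' @examples
#' toDiffusionCoefficient(0.548e-3)  # ~23 um^2/s
#' @export
toDiffusionCoefficient <- function(tauDif, calibration = FCSCalibration()) {
  if (any(tauDif <= 0)) stop("tauDif must be positive")
  calibration@DRef * calibration@tauRef / tauDif
}

#' Concentration from the fitted molecule number
#'
#' The effective detection volume is
#' `V = a * (4 * pi * DRef * tauRef)^(3/2)` (µm³, i.e. fL), and the molar
#' concentration `M = N / (N_Av * V)`.
#'
#' @param N fitted number of molecules in the detection volume.
#' @param calibration an [FCSCalibration()].
#' @return list with `volume_fL`, `concentration_nM` and `NAvogadro`.
#' @examples
#' concentration(61)$concentration_nM  # ~201 nM
#' @export
concentration <- function(N, calibration = FCSCalibration()) {
  if (any(N <= 0)) stop("N must be positive")
  NAv <- 6.02214076e23
  V <- calibration@a *
    (4 * pi * calibration@DRef * calibration@tauRef)^1.5   # um^3 == fL
  M <- N / (NAv * V * 1e-15)                               # mol/L
  list(volume_fL = V, concentration_nM = M * 1e9, NAvogadro = NAv)
}
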