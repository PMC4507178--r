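# FRAP analysis: scan-bleaching correction (double exponential with a
# multiplicative step for the confined-compartment loss), FLIP-step removal
# to residual recovery traces, double-exponential recovery fitting, and
# radial bleach-spot profiles.

.doubleExp <- function(t, A0, A1, tauA, A2, tauB)
  A0 + A1 * exp(-t / tauA) + A2 * exp(-t / tauB)

#' Correct FRAP traces for scan bleaching
#'
#' The background-subtracted compartment (nucleus / whole-cell) trace is
#' fitted with a double exponential multiplied by a step,
#' `[A0 + A1 exp(-t/tauA) + A2 exp(-t/tauB)] * [1 - s * 1(t >= t_bleach)]`:
#' the decay captures fluorescence loss due to scanning, the step `s` the
#' FLIP loss of the closed compartment at the bleach. Both traces are then
#' divided by the fitted double exponential *without* the step and scaled so
#' the pre-bleach mean is 1. An additive-step variant
#' (`stepModel = "additive"`) is retained for comparison. Falls back to a
#' single exponential (A2 = 0) when the double-exponential fit does not
#' converge.
#'
#' @param traces a [FRAPTraces-class].
#' @param stepModel `"multiplicative"` (default) or `"additive"`.
#' @param minPreBleach minimum number of pre-bleach frames.
#' @return list with `traces` (corrected [FRAPTraces-class], background 0)
#'   and `fit` (a [ScanBleachFit-class]).
#' @export
correctScanBleach <- function(traces, stepModel = c("multiplicative",
                                                    "additive"),
                              minPreBleach = 10L) {
  stepModel <- match.arg(stepModel)
  stopifnot(is(traces, "FRAPTraces"))
  if (traces@preBleachFrames < minPreBleach)
    stop("need at least ", minPreBleach, " pre-bleach frames")
  t <- traces@time
  bg <- traces@background
  comp <- traces@compartment - bg
  roi <- traces@roi - bg
  post <- t >= t[traces@bleachFrame]
  pre0 <- mean(comp[!post])

  model <- function(A0, A1, tauA, A2, tauB, s) {
    base <- .doubleExp(t, A0, A1, tauA, A2, tauB)
    if (stepModel == "multiplicative") base * (1 - s * post)
    else base - s * pre0 * post
  }
  tTot <- max(t) - min(t)
  startD <- c(A0 = pre0 * 0.85, A1 = pre0 * 0.05, tauA = tTot / 10,
              A2 = pre0 * 0.1, tauB = tTot,
              s = max(1 - mean(comp[post][1:5]) / pre0, 0.01))
  lower <- c(A0 = 0, A1 = 0, tauA = 1e-3, A2 = 0, tauB = 1e-3, s = 0)
  upper <- c(A0 = Inf, A1 = Inf, tauA = Inf, A2 = Inf, tauB = Inf,
             s = 0.999)
  fit <- .lmFit(startD, lower, upper, function(p)
    comp - model(p[["A0"]], p[["A1"]], p[["tauA"]], p[["A2"]], p[["tauB"]],
                 p[["s"]]))
  singleExp <- FALSE
  if (!fit$converged) {
    singleExp <- TRUE
    sub <- c("A0", "A1", "tauA", "s")
    fit <- .lmFit(startD[sub], lower[sub], upper[sub], function(p)
      comp - model(p[["A0"]], p[["A1"]], p[["tauA"]], 0, 1, p[["s"]]))
    if (!fit$converged)
      stop("scan-bleach fit did not converge: ", fit$message)
  }
  cf <- as.list(fit$par)
  if (singleExp) { cf$A2 <- 0; cf$tauB <- 1 }
  decay <- .doubleExp(t, cf$A0, cf$A1, cf$tauA, cf$A2, cf$tauB)
  corrComp <- comp / decay
  corrRoi <- roi / decay
  # normalize the pre-bleach mean to 1
  corrRoi <- corrRoi / mean(corrRoi[!post])
  corrComp <- corrComp / mean(corrComp[!post])
  sbFit <- new("ScanBleachFit", A0 = cf$A0, A1 = cf$A1, tauA = cf$tauA,
               A2 = cf$A2, tauB = cf$tauB, step = cf$s,
               singleExp = singleExp)
  corrected <- FRAPTraces(time = t, roi = corrRoi, compartment = corrComp,
                          background = 0,
                          bleachFrame = traces@bleachFrame,
                          preBleachFrames = traces@preBleachFrames)
  list(traces = corrected, fit = sbFit)
}

#' Residual recovery trace (FLIP-loss removal)
#'
#' Divides the post-bleach parts of the corrected ROI and compartment
#' traces by `1 - s` (the fitted compartment step), so a fully mobile pool
#' recovers to 1 and the compartment trace returns to its pre-bleach level.
#' The pre-bleach parts are unchanged. The fitted step is used rather than
#' a per-frame compartment ratio to avoid amplifying frame noise.
#'
#' @param corrected corrected [FRAPTraces-class] (see
#'   [correctScanBleach()]).
#' @param fit the corresponding [ScanBleachFit-class] (or a numeric step
#'   fraction).
#' @return the residual [FRAPTraces-class].
#' @export
residualTrace <- function(corrected, fit) {
  s <- if (is(fit, "ScanBleachFit")) fit@step else as.numeric(fit)
  if (s >= 1) stop("step fraction must be < 1")
  roi <- corrected@roi
  comp <- corrected@compartment
  post <- seq.int(corrected@bleachFrame, length(roi))
  roi[post] <- roi[post] / (1 - s)
  comp[post] <- comp[post] / (1 - s)
  FRAPTraces(time = corrected@time, roi = roi,
             compartment = comp,
             background = corrected@background,
             bleachFrame = corrected@bleachFrame,
             preBleachFrames = corrected@preBleachFrames)
}

#' Fit the double-exponential recovery model
#'
#' Fits `1 - a1 exp(-t/tau1) - a2 exp(-t/tau2)` to the post-bleach residual
#' trace, with `t = 0` at the first post-bleach frame; `tau1 <= tau2` is
#' enforced by relabelling. The immobile fraction is reported as 1 minus
#' the observed plateau (mean of the last `tailFraction` of the trace).
#' Falls back to a single exponential when the double fit fails.
#'
#' @param residual residual [FRAPTraces-class] (or a list of them, averaged
#'   frame-wise before fitting).
#' @param minPostBleach minimum number of post-bleach frames.
#' @param tailFraction fraction of trailing frames defining the plateau.
#' @return a [RecoveryFit-class].
#' @export
fitRecovery <- function(residual, minPostBleach = 30L, tailFraction = 0.1) {
  if (is.list(residual)) {
    roiMat <- vapply(residual, slot, numeric(length(residual[[1]]@roi)),
                     "roi")
    avg <- residual[[1]]
    avg@roi <- rowMeans(roiMat)
    residual <- avg
  }
  stopifnot(is(residual, "FRAPTraces"))
  post <- seq.int(residual@bleachFrame, length(residual@time))
  if (length(post) < minPostBleach)
    stop("need at least ", minPostBleach, " post-bleach frames")
  t <- residual@time[post] - residual@time[post[1]]
  y <- residual@roi[post]

  dt <- diff(residual@time[1:2])
  start <- c(a1 = max(0.6 * (1 - y[1]), 0.01), tau1 = 5 * dt,
             a2 = max(0.3 * (1 - y[1]), 0.01), tau2 = max(t) / 3)
  lower <- c(a1 = 0, tau1 = 1e-4, a2 = 0, tau2 = 1e-4)
  upper <- c(a1 = Inf, tau1 = Inf, a2 = Inf, tau2 = Inf)
  fit <- .lmFit(start, lower, upper, function(p)
    y - (1 - p[["a1"]] * exp(-t / p[["tau1"]]) -
           p[["a2"]] * exp(-t / p[["tau2"]])))
  singleExp <- FALSE
  if (!fit$converged) {
    singleExp <- TRUE
    sub <- c("a1", "tau1")
    fit <- .lmFit(start[sub], lower[sub], upper[sub], function(p)
      y - (1 - p[["a1"]] * exp(-t / p[["tau1"]])))
    if (!fit$converged)
      stop("recovery fit did not converge: ", fit$message)
  }
  cf <- as.list(fit$par)
  if (singleExp) { cf$a2 <- 0; cf$tau2 <- cf$tau1 }
  if (cf$tau1 > cf$tau2) cf <- list(a1 = cf$a2, tau1 = cf$tau2,
                                    a2 = cf$a1, tau2 = cf$tau1)
  nTail <- max(3L, ceiling(tailFraction * length(y)))
  plateau <- mean(y[(length(y) - nTail + 1L):length(y)])
  new("RecoveryFit", a1 = cf$a1, tau1 = cf$tau1, a2 = cf$a2,
      tau2 = cf$tau2, immobileFraction = 1 - plateau,
      singleExp = singleExp)
}

#' Radial fluorescence profile around the bleach centre
#'
#' Averages fluorescence in concentric rings of fixed pitch (207 nm by
#' default) around the bleach centre; pixels outside the compartment mask
#' are omitted. Rings without in-mask pixels are flagged as missing (NA).
#'
#' @param frame intensity matrix (typically the first post-bleach frame),
#'   or a list of matrices, averaged before profiling.
#' @param center bleach centre, 0-based (row, col); must lie inside the
#'   mask.
#' @param mask logical compartment mask.
#' @param pixelSize nm per px.
#' @param pitch ring thickness in nm (default = `pixelSize`).
#' @param maxRadius outer radius in nm (default: to the farthest in-mask
#'   pixel).
#' @return a [RadialProfile-class].
#' @export
radialProfile <- function(frame, center, mask, pixelSize = 207,
                          pitch = pixelSize, maxRadius = NULL) {
  if (is.list(frame)) frame <- Reduce(`+`, frame) / length(frame)
  stopifnot(identical(dim(frame), dim(mask)))
  ci <- round(center) + 1
  if (ci[1] < 1 || ci[2] < 1 || ci[1] > nrow(mask) || ci[2] > ncol(mask) ||
      !mask[ci[1], ci[2]])
    stop("bleach centre must lie inside the compartment mask")
  nr <- nrow(frame); nc <- ncol(frame)
  rowc <- matrix(seq_len(nr) - 1, nr, nc)
  colc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  rNm <- sqrt((rowc - center[1])^2 + (colc - center[2])^2) * pixelSize
  if (is.null(maxRadius)) maxRadius <- max(rNm[mask])
  ring <- floor(rNm / pitch)
  nRings <- floor(maxRadius / pitch) + 1
  inRange <- mask & ring < nRings
  idx <- ring[inRange] + 1L
  vals <- frame[inRange]
  n <- tabulate(idx, nbins = nRings)
  s <- vapply(seq_len(nRings), function(k) sum(vals[idx == k]), numeric(1))
  mu <- ifelse(n > 0, s / pmax(n, 1L), NA_real_)
  new("RadialProfile", radius = (seq_len(nRings) - 0.5) * pitch,
      mean = mu, n = as.integer(n), pitch = pitch)
}
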