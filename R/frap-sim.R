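# Synthetic FRAP inputs: ROI/compartment trace pairs with scan bleaching,
# a FLIP step loss and double-exponential recovery; and a conservative 2-D
# lattice-diffusion movie with a tornado bleach.

#' Specify a FRAP simulation
#'
#' @param mode `"trace"` or `"movie"`.
#' @param recovery recovery truth: list or preset name (see
#'   [presetTable()]`("frap")`) with `a1`, `tau1` (s), `a2`, `tau2` (s),
#'   `stepLoss` (compartment step fraction in `[0,1)`), `bleachDepth`
#'   (ROI drop at the bleach) and `immobileFraction`.
#' @param scanBleach list `A1`, `tauA` (s), `A2`, `tauB` (s) of the slow
#'   acquisition-bleaching double exponential (amplitudes are fractions of
#'   the initial level; set both to 0 to disable).
#' @param preBleachFrames,totalFrames frame counts (defaults 30 / 210).
#' @param frameInterval seconds per frame (default 0.331).
#' @param bleachDuration duration of the bleach gap between the last
#'   pre-bleach and first post-bleach frame (s).
#' @param background constant background level added to both traces.
#' @param noiseSd relative Gaussian noise sd on both traces.
#' @param pixelSize nm per px (movie mode).
#' @param gridSize movie frame size in px.
#' @param nucleusRadius,nucleolusRadius movie geometry, px.
#' @param DMap diffusion coefficients µm²/s: named list
#'   `nucleoplasm`, `nucleolus`.
#' @param bleachCenter 0-based (row, col) of the bleach; default nucleolus
#'   centre.
#' @param bleachRadius bleach radius in px (default 6).
#' @param bleachDepthMovie fraction bleached at the spot centre.
#' @param seed integer seed.
#' @export
frapSimSpec <- function(mode = c("trace", "movie"), recovery = "nucleolus",
                        scanBleach = list(A1 = 0.05, tauA = 8,
                                          A2 = 0.10, tauB = 60),
                        preBleachFrames = 30L, totalFrames = 210L,
                        frameInterval = 0.331, bleachDuration = 1,
                        background = 5, noiseSd = 0.02,
                        pixelSize = 207, gridSize = 96L,
                        nucleusRadius = 40, nucleolusRadius = 12,
                        DMap = list(nucleoplasm = 1.5, nucleolus = 0.35),
                        bleachCenter = NULL, bleachRadius = 6,
                        bleachDepthMovie = 0.8, seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(recovery)) recovery <- presetTable("frap", recovery)
  stopifnot(recovery$a1 >= 0, recovery$a2 >= 0,
            recovery$a1 + recovery$a2 <= 1,
            recovery$tau1 > 0, recovery$tau2 > 0)
  if (recovery$stepLoss < 0 || recovery$stepLoss >= 1)
    stop("stepLoss must be in [0, 1)")
  list(mode = mode, recovery = recovery, scanBleach = scanBleach,
       preBleachFrames = as.integer(preBleachFrames),
       totalFrames = as.integer(totalFrames),
       frameInterval = frameInterval, bleachDuration = bleachDuration,
       background = background, noiseSd = noiseSd, pixelSize = pixelSize,
       gridSize = as.integer(gridSize), nucleusRadius = nucleusRadius,
       nucleolusRadius = nucleolusRadius, DMap = DMap,
       bleachCenter = bleachCenter, bleachRadius = bleachRadius,
       bleachDepthMovie = bleachDepthMovie, seed = as.integer(seed))
}

# Residual recovery truth at time t after the bleach.
.recoveryCurve <- function(t, rec) {
  plateau <- 1 - rec$immobileFraction
  depth <- rec$bleachDepth
  # rescale the double exponential so the trace starts at (1 - depth) and
  # approaches the plateau with the preset time constants
  a1 <- rec$a1; a2 <- rec$a2
  scale <- if (a1 + a2 > 0) (plateau - (1 - depth)) / (a1 + a2) else 0
  plateau - scale * (a1 * exp(-t / rec$tau1) + a2 * exp(-t / rec$tau2))
}

#' Simulate FRAP data with known truth
#'
#' Trace mode emits an ROI + compartment trace pair: a pre-bleach plateau,
#' slow scan-bleaching decay, a step loss of the confined compartment at the
#' bleach, and double-exponential recovery of the ROI. Movie mode runs
#' conservative 2-D lattice diffusion inside a closed nuclear disk (no-flux
#' boundary), with a reduced diffusion coefficient inside the nucleolus and
#' a Gaussian-edged tornado bleach.
#'
#' @param spec a [frapSimSpec()].
#' @return trace mode: list with `traces` ([FRAPTraces-class]) and `truth`.
#'   Movie mode: list with `frames` (list of matrices), `time`, masks
#'   (`nucleus`, `nucleolus`), `bleachCenter`, `bleachFrame` and `truth`.
#' @export
makeFRAP <- function(spec) {
  set.seed(spec$seed)
  if (spec$mode == "trace") return(.makeFRAPTrace(spec))
  .makeFRAPMovie(spec)
}

#' Simulate a replicate set of FRAP trace pairs
#'
#' Generates `n` ROI/compartment trace pairs from one spec. Replicates are
#' drawn as antithetic noise pairs (the two members of a pair share one
#' noise realization with opposite sign), so replicate averages are centred
#' on the noise-free trace while each trace individually carries the
#' spec's noise level — the same variance-reduction design the cell
#' population generator uses.
#'
#' @param spec a [frapSimSpec()] in `trace` mode.
#' @param n number of traces.
#' @return list of `n` results as from [makeFRAP()].
#' @export
makeFRAPSeries <- function(spec, n = 6L) {
  stopifnot(spec$mode == "trace")
  set.seed(spec$seed)
  nf <- spec$totalFrames
  out <- vector("list", n)
  for (k in seq_len(ceiling(n / 2))) {
    eps <- list(roi = stats::rnorm(nf), comp = stats::rnorm(nf))
    for (s in c(1, -1)) {
      i <- 2L * (k - 1L) + if (s > 0) 1L else 2L
      if (i > n) break
      out[[i]] <- .makeFRAPTrace(spec, noiseRoi = s * eps$roi,
                                 noiseComp = s * eps$comp)
    }
  }
  out
}

.makeFRAPTrace <- function(spec, noiseRoi = NULL, noiseComp = NULL) {
  n <- spec$totalFrames
  nPre <- spec$preBleachFrames
  rec <- spec$recovery
  # frame times; the bleach occupies a gap of bleachDuration after frame nPre
  t <- (seq_len(n) - 1) * spec$frameInterval
  t[(nPre + 1):n] <- t[(nPre + 1):n] + spec$bleachDuration
  sb <- spec$scanBleach
  A0 <- 1 - sb$A1 - sb$A2
  decay <- A0 + sb$A1 * exp(-t / sb$tauA) + sb$A2 * exp(-t / sb$tauB)
  post <- seq.int(nPre + 1L, n)
  tPost <- t[post] - t[nPre + 1L]

  stepFac <- rep(1, n); stepFac[post] <- 1 - rec$stepLoss
  compartment <- decay * stepFac

  roi <- decay
  roi[post] <- decay[post] * (1 - rec$stepLoss) * .recoveryCurve(tPost, rec)

  if (spec$noiseSd > 0) {
    if (is.null(noiseRoi)) noiseRoi <- stats::rnorm(n)
    if (is.null(noiseComp)) noiseComp <- stats::rnorm(n)
    roi <- roi * (1 + spec$noiseSd * noiseRoi)
    compartment <- compartment * (1 + spec$noiseSd * noiseComp)
  }
  traces <- FRAPTraces(time = (seq_len(n) - 1) * spec$frameInterval,
                       roi = roi + spec$background,
                       compartment = compartment + spec$background,
                       background = spec$background,
                       bleachFrame = nPre + 1L, preBleachFrames = nPre)
  list(traces = traces, truth = rec)
}

.makeFRAPMovie <- function(spec) {
  n <- spec$gridSize
  rowc <- matrix(seq_len(n) - 1, n, n)
  colc <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  ctr <- (n - 1) / 2
  rNuc <- sqrt((rowc - ctr)^2 + (colc - ctr)^2)
  nucleus <- rNuc <= spec$nucleusRadius
  nuCtr <- c(ctr - spec$nucleusRadius * 0.35, ctr + spec$nucleusRadius * 0.3)
  rNo <- sqrt((rowc - nuCtr[1])^2 + (colc - nuCtr[2])^2)
  nucleolus <- rNo <= spec$nucleolusRadius & nucleus

  if (is.null(spec$bleachCenter)) spec$bleachCenter <- nuCtr
  bd <- sqrt((rowc - spec$bleachCenter[1])^2 + (colc - spec$bleachCenter[2])^2)
  if (sqrt(sum((spec$bleachCenter - ctr)^2)) + spec$bleachRadius >
        spec$nucleusRadius)
    stop("bleach circle must lie inside the nucleus")

  h <- spec$pixelSize * 1e-3                       # um
  D <- matrix(0, n, n)
  D[nucleus] <- spec$DMap$nucleoplasm
  D[nucleolus] <- spec$DMap$nucleolus
  dt <- 0.5 * h^2 / (4 * max(D))
  stepsPerFrame <- max(1L, ceiling(spec$frameInterval / dt))
  dt <- spec$frameInterval / stepsPerFrame

  img <- matrix(0, n, n); img[nucleus] <- 1
  # flux-form update: conserves total intensity exactly on a closed domain
  # (harmonic-mean edge D; D = 0 outside the nucleus gives no-flux walls)
  edgeD <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  Dr <- edgeD(D[-n, ], D[-1, ])    # vertical edges
  Dc <- edgeD(D[, -n], D[, -1])    # horizontal edges
  lam <- dt / h^2
  diffuseFrame <- function(img, nSteps) {
    for (s in seq_len(nSteps)) {
      fr <- lam * Dr * (img[-1, ] - img[-n, ])
      fc <- lam * Dc * (img[, -1] - img[, -n])
      img[-n, ] <- img[-n, ] + fr
      img[-1, ] <- img[-1, ] - fr
      img[, -n] <- img[, -n] + fc
      img[, -1] <- img[, -1] - fc
    }
    img
  }

  frames <- vector("list", spec$totalFrames)
  nPre <- spec$preBleachFrames
  for (k in seq_len(nPre)) frames[[k]] <- img
  # tornado bleach: Gaussian-edged circular depression
  bleachProfile <- 1 - spec$bleachDepthMovie *
    stats::pnorm((spec$bleachRadius - bd) / 1.5)
  img <- img * bleachProfile
  img[!nucleus] <- 0
  bleachSteps <- max(1L, ceiling(spec$bleachDuration / dt))
  img <- diffuseFrame(img, min(bleachSteps, 4L * stepsPerFrame))
  for (k in seq.int(nPre + 1L, spec$totalFrames)) {
    frames[[k]] <- img
    img <- diffuseFrame(img, stepsPerFrame)
  }
  if (spec$noiseSd > 0)
    frames <- lapply(frames, function(f)
      f * (1 + matrix(stats::rnorm(n * n, 0, spec$noiseSd), n, n)))
  list(frames = frames, time = (seq_len(spec$totalFrames) - 1) * spec$frameInterval,
       nucleus = nucleus, nucleolus = nucleolus,
       bleachCenter = spec$bleachCenter, bleachFrame = nPre + 1L,
       truth = list(DMap = spec$DMap, bleachRadius = spec$bleachRadius,
                    bleachDepth = spec$bleachDepthMovie))
}
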