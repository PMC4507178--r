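# Synthetic three-channel cell phantoms with known ground truth.
#
# The phantom is a single cell: an elliptical cytoplasm, an elliptical
# nucleus and disk nucleoli with 1-px Gaussian edge softening (so threshold
# steps see realistic partial-volume pixels). Channel model, before shading,
# offset and noise, with p the (soft) nucleolus indicator and f the freely
# accessible volume fraction inside nucleoli:
#
#   reference = L_ref * (1 - (1 - f) * p)              in the nucleus
#   construct = L_con * (1 - (1 - (1 + R) * f) * p)    in the nucleus
#   marker    = L_mrk * (1 + (gc-1)*p + (dfc-gc)*pInner)
#
# so the normalized construct level inside a nucleolus is (1 + R) * f and the
# adjusted nucleolus/nucleoplasm ratio of the construct is exactly R.

#' Specify a synthetic cell phantom
#'
#' @param imageSize image dimensions in pixels (rows, cols).
#' @param pixelSize pixel size in nm.
#' @param nucleusCenter nucleus centre, 0-based (row, col); default image
#'   centre.
#' @param nucleusAxes nucleus ellipse semi-axes in px (row, col).
#' @param cellAxes cytoplasm (whole cell) ellipse semi-axes in px.
#' @param nNucleoli number of nucleoli.
#' @param nucleolusRadii radii in px, recycled to `nNucleoli`.
#' @param accessibleFraction f, reference-channel level inside nucleoli
#'   relative to the nucleoplasm, in (0, 1].
#' @param enrichmentR construct excess enrichment R (adjusted-ratio truth).
#' @param cytoNpRef raw cytoplasm/nucleoplasm ratio of the reference channel.
#' @param cytoNpConstructNorm construct cytoplasm/nucleoplasm ratio relative
#'   to the reference channel (1 = reference-like).
#' @param levels nucleoplasm intensity per channel
#'   (`marker`, `reference`, `construct`).
#' @param markerGC,markerDFC marker enrichment of the granular component and
#'   the (inner-disk) dense fibrillar component, relative to nucleoplasm.
#' @param dfcRadiusFraction inner-disk radius as a fraction of the nucleolus
#'   radius.
#' @param edgeSigma Gaussian edge softening of nucleolus disks, px.
#' @param shadingAmplitude amplitude of the multiplicative low-order
#'   polynomial shading along the slow (column) scan axis; 0 disables.
#' @param offset additive detector offset (background level).
#' @param noise list with `poissonScale` (detected counts per intensity
#'   unit; 0 disables shot noise) and `readSd` (Gaussian read noise sd);
#'   or the string `"off"`.
#' @param fragmented render each nucleolus as a ring of small remnants
#'   (disrupted-nucleolus morphology) instead of a solid disk.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return a validated spec (list) for [makeCellImage()].
#' @export
cellPhantomSpec <- function(imageSize = c(512L, 512L), pixelSize = 207,
                            nucleusCenter = NULL,
                            nucleusAxes = c(95, 120), cellAxes = c(160, 210),
                            nNucleoli = 3L, nucleolusRadii = c(16, 12, 10),
                            accessibleFraction = 0.5, enrichmentR = 0,
                            cytoNpRef = 0.89, cytoNpConstructNorm = 1,
                            levels = c(marker = 80, reference = 100,
                                       construct = 120),
                            markerGC = 3, markerDFC = 6,
                            dfcRadiusFraction = 0.45, edgeSigma = 1,
                            shadingAmplitude = 0.15, offset = 20,
                            noise = list(poissonScale = 2, readSd = 1.5),
                            fragmented = FALSE, seed = 1L) {
  if (identical(noise, "off")) noise <- list(poissonScale = 0, readSd = 0)
  if (is.null(nucleusCenter)) nucleusCenter <- (imageSize - 1) / 2
  spec <- list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
               nucleusCenter = nucleusCenter, nucleusAxes = nucleusAxes,
               cellAxes = cellAxes, nNucleoli = as.integer(nNucleoli),
               nucleolusRadii = rep_len(nucleolusRadii, nNucleoli),
               accessibleFraction = accessibleFraction,
               enrichmentR = enrichmentR, cytoNpRef = cytoNpRef,
               cytoNpConstructNorm = cytoNpConstructNorm, levels = levels,
               markerGC = markerGC, markerDFC = markerDFC,
               dfcRadiusFraction = dfcRadiusFraction, edgeSigma = edgeSigma,
               shadingAmplitude = shadingAmplitude, offset = offset,
               noise = noise, fragmented = isTRUE(fragmented),
               seed = as.integer(seed))
  .validatePhantomSpec(spec)
  spec
}

.validatePhantomSpec <- function(spec) {
  stopifnot(spec$pixelSize > 0,
            spec$accessibleFraction > 0, spec$accessibleFraction <= 1,
            spec$enrichmentR > -1,
            all(spec$levels > 0), spec$cytoNpRef > 0,
            all(spec$nucleolusRadii > 0),
            all(spec$nucleusAxes < spec$cellAxes))
  invisible(TRUE)
}

# Deterministic nucleolus placement: spread centres on an inner ellipse at
# fixed angles (jittered by the seed) and reject specs whose nucleoli touch
# the nucleus boundary.
.placeNucleoli <- function(spec) {
  k <- spec$nNucleoli
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  ang <- 2 * pi * (seq_len(k) - 1) / k + stats::runif(1, 0, 2 * pi)
  rad <- stats::runif(k, 0.25, 0.55)
  centers <- cbind(
    spec$nucleusCenter[1] + rad * spec$nucleusAxes[1] * sin(ang),
    spec$nucleusCenter[2] + rad * spec$nucleusAxes[2] * cos(ang))
  margin <- spec$nucleolusRadii + 3 * spec$edgeSigma + 2
  u <- ((centers[, 1] - spec$nucleusCenter[1]) / (spec$nucleusAxes[1] - margin))^2 +
       ((centers[, 2] - spec$nucleusCenter[2]) / (spec$nucleusAxes[2] - margin))^2
  if (any(margin >= min(spec$nucleusAxes)) || any(u >= 1))
    stop("nucleoli overlap the nucleus boundary; reduce radii or count")
  centers
}

#' Render a synthetic three-channel cell image
#'
#' Generates marker / reference / construct channels plus ground-truth masks
#' and ratios. The truth [MaskSet-class] uses the half-level (p >= 0.5)
#' contour for the nucleolar masks; `truth$coreLabels` additionally labels
#' pure-interior pixels (p > 0.999), on which the generative model holds
#' without partial-volume mixing.
#'
#' @param spec a [cellPhantomSpec()].
#' @return list with `image` ([MultiChannelImage-class]) and `truth` (list:
#'   `masks` [MaskSet-class], `coreLabels`, `enrichmentR`, `cytoNpRef`,
#'   `cytoNpConstructRaw`, `accessibleFraction`, `nucleolusCenters`).
#' @examples
#' ph <- makeCellImage(cellPhantomSpec(imageSize = c(128, 128),
#'   nucleusAxes = c(40, 50), cellAxes = c(55, 62),
#'   nucleolusRadii = c(9, 7, 6), noise = "off", shadingAmplitude = 0))
#' ph$image
#' @export
makeCellImage <- function(spec) {
  .validatePhantomSpec(spec)
  set.seed(spec$seed)
  nr <- spec$imageSize[1]; nc <- spec$imageSize[2]
  rowc <- matrix(seq_len(nr) - 1, nr, nc)
  colc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)

  inEllipse <- function(center, axes) {
    ((rowc - center[1]) / axes[1])^2 + ((colc - center[2]) / axes[2])^2 <= 1
  }
  cellMask <- inEllipse(spec$nucleusCenter, spec$cellAxes)
  nucleus <- inEllipse(spec$nucleusCenter, spec$nucleusAxes)
  cytoplasm <- cellMask & !nucleus

  centers <- .placeNucleoli(spec)
  softDisk <- function(center, radius) {
    d <- sqrt((rowc - center[1])^2 + (colc - center[2])^2)
    stats::pnorm((radius - d) / spec$edgeSigma)
  }
  p <- matrix(0, nr, nc); pInner <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc); coreLabels <- matrix(0L, nr, nc)
  for (i in seq_len(spec$nNucleoli)) {
    r <- spec$nucleolusRadii[i]
    if (spec$fragmented) {
      # disrupted morphology: ring of small remnants around the old centre
      nFrag <- 4L
      fa <- 2 * pi * seq_len(nFrag) / nFrag + stats::runif(1, 0, 2 * pi)
      pi_i <- matrix(0, nr, nc)
      for (j in seq_len(nFrag)) {
        fc <- centers[i, ] + 0.9 * r * c(sin(fa[j]), cos(fa[j]))
        pi_i <- pmax(pi_i, softDisk(fc, r / 2.6))
      }
    } else {
      pi_i <- softDisk(centers[i, ], r)
    }
    labels[pi_i >= 0.5 & labels == 0L] <- i
    # pure-interior pixels: beyond 5 edge sigmas, where partial-volume
    # mixing is below 3e-7 and the generative pixel model holds exactly
    coreLabels[pi_i >= stats::pnorm(5) & coreLabels == 0L] <- i
    p <- pmax(p, pi_i)
    pInner <- pmax(pInner, softDisk(centers[i, ], r * spec$dfcRadiusFraction))
  }
  p <- p * nucleus; pInner <- pInner * nucleus
  labels[!nucleus] <- 0L; coreLabels[!nucleus] <- 0L

  f <- spec$accessibleFraction; R <- spec$enrichmentR
  L <- spec$levels
  cytoRef <- spec$cytoNpRef
  cytoCon <- spec$cytoNpConstructNorm * cytoRef

  reference <- L[["reference"]] * (nucleus * (1 - (1 - f) * p) +
                                   cytoplasm * cytoRef)
  construct <- L[["construct"]] * (nucleus * (1 - (1 - (1 + R) * f) * p) +
                                   cytoplasm * cytoCon)
  marker <- L[["marker"]] * (nucleus * (1 + (spec$markerGC - 1) * p +
                                        (spec$markerDFC - spec$markerGC) * pInner) +
                             cytoplasm * 0.3)

  shade <- if (spec$shadingAmplitude > 0) {
    u <- (seq_len(nc) - 1) / (nc - 1)
    1 + spec$shadingAmplitude * (u - 0.5) + spec$shadingAmplitude * (u - 0.5)^2
  } else rep(1, nc)
  applyNoise <- function(m) {
    m <- sweep(m, 2L, shade, `*`) + spec$offset
    if (spec$noise$poissonScale > 0)
      m <- matrix(stats::rpois(length(m), as.vector(m) * spec$noise$poissonScale),
                  nr, nc) / spec$noise$poissonScale
    if (spec$noise$readSd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$noise$readSd), nr, nc)
    pmax(m, 0)
  }
  img <- MultiChannelImage(
    list(marker = applyNoise(marker), reference = applyNoise(reference),
         construct = applyNoise(construct)),
    pixelSize = spec$pixelSize)

  # background truth ROI: a corner patch guaranteed outside the cell
  background <- matrix(FALSE, nr, nc)
  bgSide <- max(8L, min(24L, floor(min(nr, nc) / 8)))
  background[seq_len(bgSide), seq_len(bgSide)] <- TRUE
  if (any(background & cellMask))
    background <- background & !cellMask

  final <- labels > 0L
  masks <- new("MaskSet", background = background, cytoplasm = cytoplasm,
               nucleus = nucleus, nucleolarInitial = final,
               nucleolarFinal = final, nucleolarLabels = labels,
               nucleoplasm = nucleus & !final,
               provenance = list(source = "phantom ground truth"))
  list(image = img,
       truth = list(masks = masks, coreLabels = coreLabels,
                    enrichmentR = R, cytoNpRef = cytoRef,
                    cytoNpConstructRaw = cytoCon,
                    accessibleFraction = f, nucleolusCenters = centers,
                    nucleolusProfile = p))
}

#' Simulate a population of cells from a named preset
#'
#' Draws per-cell enrichment and cytoplasm/nucleoplasm values around the
#' preset means (spreads back-calculated from the reported 95% CIs), jitters
#' the geometry, and renders each cell.
#'
#' @param preset a cell preset name (see [presetTable()]).
#' @param n number of cells.
#' @param seed integer seed for the population.
#' @param imageSize,... overrides passed to [cellPhantomSpec()].
#' @return list of [makeCellImage()] results, one per cell.
#' @export
simulateCells <- function(preset, n = 20L, seed = 1L,
                          imageSize = c(256L, 256L), ...) {
  par <- presetTable("cell", preset)
  set.seed(seed)
  # antithetic standard-normal draws: z and -z pairwise, so the sample mean
  # of the per-cell parameters is centred on the preset value (variance
  # reduction for population-mean validation; the marginal is unchanged)
  antithetic <- function(n) {
    z <- stats::rnorm(ceiling(n / 2))
    c(rbind(z, -z))[seq_len(n)]
  }
  draws <- data.frame(
    R = pmax(par$enrichmentR + par$enrichmentSd * antithetic(n), -0.95),
    cytoRef = pmax(par$cytoNpRef + par$cytoNpRefSd * antithetic(n), 0.05),
    nNu = sample(2:3, n, replace = TRUE),
    geom = stats::runif(n, 0.9, 1.1),
    cellSeed = sample.int(.Machine$integer.max, n))
  base <- min(imageSize) / 256
  lapply(seq_len(n), function(i) {
    spec <- cellPhantomSpec(
      imageSize = imageSize,
      nucleusAxes = base * draws$geom[i] * c(48, 60),
      cellAxes = base * draws$geom[i] * c(80, 105),
      nNucleoli = draws$nNu[i],
      nucleolusRadii = base * draws$geom[i] * c(13, 10, 8)[seq_len(draws$nNu[i])],
      enrichmentR = draws$R[i], cytoNpRef = draws$cytoRef[i],
      cytoNpConstructNorm = par$cytoNpConstructNorm,
      fragmented = isTRUE(par$fragmented),
      seed = draws$cellSeed[i], ...)
    makeCellImage(spec)
  })
}
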