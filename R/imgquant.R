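# Three-channel localization quantification: background subtraction, the
# staged nucleolar mask pipeline, cytoplasm/nucleoplasm ratios, raw and
# inaccessible-volume-corrected ("adjusted") nucleolus/nucleoplasm ratios.

#' Subtract mean background fluorescence per channel
#'
#' The mean intensity of a cell-free background ROI is subtracted from each
#' channel; negative values are clipped at zero.
#'
#' @param image a [MultiChannelImage-class].
#' @param backgroundRoi logical matrix, TRUE over a cell-free region of at
#'   least `minPixels` pixels.
#' @param minPixels minimum ROI size.
#' @return the background-subtracted [MultiChannelImage-class].
#' @export
subtractBackground <- function(image, backgroundRoi, minPixels = 50L) {
  stopifnot(is(image, "MultiChannelImage"))
  if (!identical(dim(backgroundRoi), dim(image)))
    stop("background ROI dimensions do not match the image")
  npx <- sum(backgroundRoi)
  if (npx == 0L) stop("background ROI is empty")
  if (npx < minPixels)
    stop("background ROI has ", npx, " px; need at least ", minPixels)
  image@channels <- lapply(image@channels, function(m)
    pmax(m - mean(m[backgroundRoi]), 0))
  image
}

#' Cytoplasm/nucleoplasm median-fluorescence ratio
#'
#' Raw ratio = median(cytoplasm) / median(nucleoplasm) per channel. The
#' normalized ratio divides the construct's raw ratio by the reference
#' channel's raw ratio, removing cell-geometry and organelle contributions;
#' a value of 1 means the construct partitions like the free reference.
#'
#' @param image background-subtracted [MultiChannelImage-class].
#' @param cytoplasmRoi,nucleoplasmMask logical matrices.
#' @param channel channel to measure (default `"construct"`).
#' @param referenceChannel channel used for normalization (default
#'   `"reference"`).
#' @return list with `raw`, `rawReference` and `normalized`.
#' @export
cytoNpRatio <- function(image, cytoplasmRoi, nucleoplasmMask,
                        channel = "construct",
                        referenceChannel = "reference") {
  if (!any(cytoplasmRoi) || !any(nucleoplasmMask))
    stop("cytoplasm ROI and nucleoplasm mask must both be non-empty")
  ratioOf <- function(ch) {
    m <- channel(image, ch)
    npMed <- stats::median(m[nucleoplasmMask])
    if (npMed == 0) stop("zero nucleoplasm median in channel '", ch, "'")
    stats::median(m[cytoplasmRoi]) / npMed
  }
  raw <- ratioOf(channel)
  rawRef <- ratioOf(referenceChannel)
  list(raw = raw, rawReference = rawRef, normalized = raw / rawRef)
}

#' Build the staged nucleolar mask set
#'
#' Implements the mask pipeline, in order:
#' 1. mode-normalize the marker and reference channels inside the nucleus
#'    ROI (histogram mode, bin width 1% of the intensity range);
#' 2. initial nucleolar mask = marker/reference ratio image > `ratioThreshold`
#'    (default 2.0);
#' 3. initial nucleoplasm mask = nucleus minus initial nucleolar mask;
#' 4. per channel, compute the column mean profile (slow scan axis) over
#'    initial-nucleoplasm pixels, smooth with an 11-px boxcar, and divide the
#'    nucleus pixels by it, so the nucleoplasm is normalized to 1;
#' 5. final nucleolar mask = normalized marker > `markerThreshold`
#'    (default 1.4);
#' 6. final nucleoplasm mask = nucleus minus final nucleolar mask;
#' 7. per selected nucleolus (connected components of at least `minArea`
#'    px, or an explicit label list), smooth the normalized reference with a
#'    7x7 Gaussian (sigma 200 nm), take the full-width-half-minimum level
#'    `(1 + regional minimum) / 2`, and keep pixels strictly below it.
#'
#' @param image background-subtracted [MultiChannelImage-class].
#' @param nucleusRoi logical matrix enclosing the nucleoli, excluding
#'   cytoplasm.
#' @param backgroundRoi logical matrix (stored for provenance).
#' @param cytoplasmRoi logical matrix (stored for provenance).
#' @param config an [analysisConfig()]; thresholds default to 2.0, 1.4,
#'   boxcar 11, Gaussian 7x7 / 200 nm, minimum nucleolus area 20 px.
#' @param selectNucleoli optional integer vector of component labels to
#'   keep, overriding the automatic size-based selection.
#' @return list with `masks` ([MaskSet-class]) and `normalized`
#'   (the profile-normalized [MultiChannelImage-class]; nucleoplasm = 1).
#' @export
buildMasks <- function(image, nucleusRoi, backgroundRoi = NULL,
                       cytoplasmRoi = NULL, config = analysisConfig(),
                       selectNucleoli = NULL) {
  stopifnot(is(image, "MultiChannelImage"))
  if (!any(nucleusRoi)) stop("nucleus ROI is empty")
  marker <- channel(image, "marker")
  reference <- channel(image, "reference")
  d <- dim(marker)

  # (1) mode normalization inside the nucleus ROI
  modeM <- histogramMode(marker[nucleusRoi], config$modeBinFraction)
  modeR <- histogramMode(reference[nucleusRoi], config$modeBinFraction)
  if (modeM <= 0 || modeR <= 0) stop("non-positive channel mode in nucleus ROI")
  ratioImg <- (marker / modeM) / pmax(reference / modeR, .Machine$double.eps)

  # (2)-(3) initial masks from the ratio image
  initial <- ratioImg > config$ratioThreshold & nucleusRoi
  initialNp <- nucleusRoi & !initial
  if (!any(initialNp)) stop("initial nucleoplasm mask is empty")

  # (4) per-channel column-profile normalization over the nucleus
  normalized <- lapply(image@channels, function(m) {
    colSumNp <- colSums(m * initialNp)
    colNNp <- colSums(initialNp)
    profile <- ifelse(colNNp > 0, colSumNp / pmax(colNNp, 1L), NA_real_)
    # fill columns without nucleoplasm pixels from their neighbours
    idx <- which(!is.na(profile))
    if (length(idx) == 0L) stop("no nucleoplasm pixels in any column")
    profile <- stats::approx(idx, profile[idx], xout = seq_along(profile),
                             rule = 2)$y
    profile <- boxcarSmooth(profile, config$boxcarWidth)
    if (any(profile <= 0)) stop("non-positive column profile")
    out <- sweep(m, 2L, profile, `/`)
    out[!nucleusRoi] <- m[!nucleusRoi] / mean(profile[colSums(nucleusRoi) > 0])
    out
  })
  normImage <- MultiChannelImage(normalized, pixelSize = image@pixelSize,
                                 bitDepth = image@bitDepth)

  # (5)-(6) final masks from the normalized marker
  final <- channel(normImage, "marker") > config$markerThreshold & nucleusRoi
  nucleoplasm <- nucleusRoi & !final

  # (7) refinement per nucleolus via the reference-channel half-minimum
  sigmaPx <- config$gaussianSigmaNm / image@pixelSize
  refSmooth <- convolve2d(channel(normImage, "reference"),
                          gaussianKernel(config$gaussianSize, sigmaPx))
  labels <- matrix(0L, d[1], d[2])
  fwhmLevels <- numeric(0)
  if (any(final)) {
    comp <- EBImage::bwlabel(final)
    sizes <- tabulate(comp[comp > 0])
    keep <- if (is.null(selectNucleoli)) which(sizes >= config$minNucleolusArea)
            else selectNucleoli
    newLab <- 0L
    for (k in keep) {
      region <- comp == k
      if (!any(region)) next
      regMin <- min(refSmooth[region])
      level <- (1 + regMin) / 2       # half-depth of the accessible-volume dip
      refined <- region & refSmooth < level
      if (!any(refined)) next
      newLab <- newLab + 1L
      labels[refined] <- newLab
      fwhmLevels <- c(fwhmLevels, level)
    }
  }

  masks <- new("MaskSet",
    background = if (is.null(backgroundRoi)) matrix(FALSE, d[1], d[2])
                 else backgroundRoi,
    cytoplasm = if (is.null(cytoplasmRoi)) matrix(FALSE, d[1], d[2])
                else cytoplasmRoi,
    nucleus = nucleusRoi, nucleolarInitial = initial,
    nucleolarFinal = final, nucleolarLabels = labels,
    nucleoplasm = nucleoplasm,
    provenance = list(modeMarker = modeM, modeReference = modeR,
                      ratioThreshold = config$ratioThreshold,
                      markerThreshold = config$markerThreshold,
                      boxcarWidth = config$boxcarWidth,
                      gaussianSigmaNm = config$gaussianSigmaNm,
                      minNucleolusArea = config$minNucleolusArea,
                      fwhmLevels = fwhmLevels))
  list(masks = masks, normalized = normImage)
}

#' Raw nucleolus/nucleoplasm ratio per nucleolus and per cell
#'
#' The raw ratio of a nucleolus is the mean of the normalized construct
#' pixels inside its refined mask (the nucleoplasm is normalized to 1); the
#' cell value is the area-weighted mean over its nucleoli.
#'
#' @param normImage profile-normalized image (see [buildMasks()]).
#' @param masks a [MaskSet-class] with refined nucleolar labels.
#' @param channel channel to quantify.
#' @return list with `perNucleolus` (data.frame `label`, `area`, `ratio`)
#'   and `cell` (area-weighted mean), or NULL cell value when no nucleoli
#'   were refined.
#' @export
rawNucleolarRatio <- function(normImage, masks, channel = "construct") {
  labs <- masks@nucleolarLabels
  ids <- setdiff(sort(unique(as.vector(labs))), 0L)
  if (length(ids) == 0L) {
    message("no refined nucleoli; cell excluded")
    return(list(perNucleolus = data.frame(label = integer(0),
                                          area = integer(0),
                                          ratio = numeric(0)),
                cell = NULL))
  }
  m <- channel(normImage, channel)
  per <- do.call(rbind, lapply(ids, function(k) {
    px <- labs == k
    data.frame(label = k, area = sum(px), ratio = mean(m[px]))
  }))
  list(perNucleolus = per,
       cell = sum(per$ratio * per$area) / sum(per$area))
}

#' Adjusted (inaccessible-volume-corrected) nucleolus/nucleoplasm ratio
#'
#' Corrects nucleolar enrichment for the partially inaccessible nucleolar
#' volume using the free-reference channel as the accessible-volume map.
#' With `F_i` the normalized construct and `f_i` the normalized reference
#' intensity of nucleolar pixel i (nucleoplasm = 1 in both), the
#' least-squares through-origin slope is
#' `slope = sum(F_i * f_i) / sum(f_i^2)`, and the reported adjusted ratio is
#' `slope - 1`, so a construct that distributes like the free reference
#' scores 0. The raw slope is also returned (on that convention a
#' reference-like construct scores 1).
#'
#' @param constructPixels normalized construct intensities `F_i`.
#' @param referencePixels normalized reference intensities `f_i`, in
#'   (0, 1.5].
#' @param minPixels minimum number of pixel pairs.
#' @return list with `adjusted` (slope - 1) and `slope`.
#' @export
adjustedRatio <- function(constructPixels, referencePixels,
                          minPixels = 10L) {
  if (length(constructPixels) != length(referencePixels))
    stop("pixel vectors must have equal length")
  if (length(constructPixels) < minPixels)
    stop("need at least ", minPixels, " pixel pairs")
  if (all(referencePixels == 0))
    stop("all reference pixels are zero: no accessible volume")
  if (any(referencePixels < 0 | referencePixels > 1.5))
    stop("reference pixels outside (0, 1.5]; is the image normalized?")
  slope <- sum(constructPixels * referencePixels) / sum(referencePixels^2)
  list(adjusted = slope - 1, slope = slope)
}

#' Quantify one cell end to end
#'
#' Runs background subtraction, mask construction, the
#' cytoplasm/nucleoplasm ratio and the raw and adjusted nucleolar ratios
#' for a single cell.
#'
#' @param image a [MultiChannelImage-class].
#' @param nucleusRoi,cytoplasmRoi,backgroundRoi logical matrices.
#' @param config an [analysisConfig()].
#' @return list with `cyto` (see [cytoNpRatio()]), `raw`
#'   (see [rawNucleolarRatio()]), `adjusted`, `slope`, `masks`,
#'   `normalized`.
#' @export
quantifyCell <- function(image, nucleusRoi, cytoplasmRoi, backgroundRoi,
                         config = analysisConfig()) {
  image <- subtractBackground(image, backgroundRoi,
                              minPixels = config$minBackgroundArea)
  mk <- buildMasks(image, nucleusRoi, backgroundRoi, cytoplasmRoi,
                   config = config)
  masks <- mk$masks
  cyto <- cytoNpRatio(image, cytoplasmRoi, masks@nucleoplasm)
  raw <- rawNucleolarRatio(mk$normalized, masks)
  adj <- NULL
  if (!is.null(raw$cell)) {
    # partial-volume guard: pixels straddling the refined contour mix
    # nucleoplasm and nucleolar signal within the edge/PSF scale and bias
    # the through-origin slope downward; erode the pixel set before fitting
    px <- binaryErode(masks@nucleolarLabels > 0L,
                      config$partialVolumeGuardPx)
    if (sum(px) < 10L) px <- masks@nucleolarLabels > 0L
    adj <- adjustedRatio(channel(mk$normalized, "construct")[px],
                         pmin(channel(mk$normalized, "reference")[px], 1.5))
  }
  list(cyto = cyto, raw = raw,
       adjusted = if (is.null(adj)) NA_real_ else adj$adjusted,
       slope = if (is.null(adj)) NA_real_ else adj$slope,
       masks = masks, normalized = mk$normalized)
}

#' Quantify a population of phantom cells
#'
#' Convenience wrapper running [quantifyCell()] over the output of
#' [simulateCells()] (using each phantom's ground-truth ROIs as the
#' manually drawn regions) and summarizing per-cell ratios with t-based
#' 95% confidence intervals.
#'
#' @param cells list of phantom cells from [simulateCells()].
#' @param config an [analysisConfig()].
#' @return a [RatioSummary-class].
#' @export
quantifyPopulation <- function(cells, config = analysisConfig()) {
  rows <- list(); nuRows <- list()
  for (i in seq_along(cells)) {
    ph <- cells[[i]]
    tm <- ph$truth$masks
    q <- quantifyCell(ph$image, nucleusRoi = tm@nucleus,
                      cytoplasmRoi = tm@cytoplasm,
                      backgroundRoi = tm@background, config = config)
    rows[[i]] <- data.frame(
      cell = i, cytoNpRaw = q$cyto$raw, cytoNpRawReference = q$cyto$rawReference,
      cytoNpNorm = q$cyto$normalized,
      rawRatio = if (is.null(q$raw$cell)) NA_real_ else q$raw$cell,
      adjustedRatio = q$adjusted, slope = q$slope,
      nNucleoli = nrow(q$raw$perNucleolus))
    if (nrow(q$raw$perNucleolus) > 0L)
      nuRows[[i]] <- cbind(cell = i, q$raw$perNucleolus)
  }
  cellsDf <- do.call(rbind, rows)
  nucleoli <- if (length(nuRows)) do.call(rbind, nuRows)
              else data.frame(cell = integer(0), label = integer(0),
                              area = integer(0), ratio = numeric(0))
  pop <- list(
    cytoNpRaw = populationSummary(cellsDf$cytoNpRawReference),
    cytoNpNorm = populationSummary(cellsDf$cytoNpNorm),
    rawRatio = populationSummary(cellsDf$rawRatio),
    adjustedRatio = populationSummary(cellsDf$adjustedRatio))
  new("RatioSummary", cells = cellsDf, nucleoli = nucleoli,
      population = pop)
}
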