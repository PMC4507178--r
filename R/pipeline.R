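# Batch entry point binding the modules: each subcommand reads/writes files
# under an output directory, logs the effective parameters, and is
# deterministic given the config seed.

.logLine <- function(logPath, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(line)
  if (!is.null(logPath)) cat(line, "\n", file = logPath, append = TRUE)
}

#' Run an analysis pipeline subcommand
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`preset`, `n`: render phantom cells; writes per-cell
#'     channel TIFFs, ROI-mask TIFFs (background, cytoplasm, nucleus pages)
#'     and `truth.csv`.}
#'   \item{ratio}{`inputDir` (a `simulate` output): quantify every cell;
#'     writes `ratios.csv`, `nucleoli.csv` and `population.json`.}
#'   \item{coloc}{`image`, `pair`, `mode`: scatter analysis of one image;
#'     writes `scatter.csv` and a summary JSON.}
#'   \item{fcs-fit}{`acf` (curve CSV), optional `fixA`: fit the
#'     autocorrelation model; writes `fcs_fit.json`.}
#'   \item{frap-fit}{`traces` (CSV), `preBleach`: correction chain plus
#'     recovery fit; writes `frap_fit.json` and `corrected.csv`.}
#'   \item{report}{`inputDir` holding `ratios.csv`: population summary to
#'     `report.json`.}
#' }
#'
#' @param subcommand one of the above.
#' @param args named list of subcommand arguments.
#' @param outDir output directory (created if needed).
#' @param config an [analysisConfig()]; its `seed` drives all randomness.
#' @return list of written file paths, invisibly.
#' @export
runPipeline <- function(subcommand, args = list(), outDir = ".",
                        config = analysisConfig()) {
  known <- c("simulate", "ratio", "coloc", "fcs-fit", "frap-fit", "report")
  if (!subcommand %in% known)
    stop("unknown subcommand '", subcommand, "'; usage: one of ",
         paste(known, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  .logLine(logPath, "subcommand: ", subcommand, "; seed: ", config$seed)
  writeConfig(config, file.path(outDir, "config_echo.yaml"))
  out <- switch(subcommand,
    "simulate" = .cmdSimulate(args, outDir, config, logPath),
    "ratio" = .cmdRatio(args, outDir, config, logPath),
    "coloc" = .cmdColoc(args, outDir, config, logPath),
    "fcs-fit" = .cmdFcsFit(args, outDir, config, logPath),
    "frap-fit" = .cmdFrapFit(args, outDir, config, logPath),
    "report" = .cmdReport(args, outDir, config, logPath))
  invisible(c(out, log = logPath))
}

.cmdSimulate <- function(args, outDir, config, logPath) {
  preset <- args$preset %||% "SNAILA-FL"
  n <- as.integer(args$n %||% 5L)
  cells <- simulateCells(preset, n = n, seed = config$seed)
  files <- character(0)
  truthRows <- list()
  for (i in seq_along(cells)) {
    imgPath <- file.path(outDir, sprintf("cell_%03d.tif", i))
    writeImage(cells[[i]]$image, imgPath)
    tm <- cells[[i]]$truth$masks
    maskPath <- file.path(outDir, sprintf("cell_%03d_rois.tif", i))
    writeImage(list(background = tm@background * 65535,
                    cytoplasm = tm@cytoplasm * 65535,
                    nucleus = tm@nucleus * 65535), maskPath)
    files <- c(files, imgPath, maskPath)
    truthRows[[i]] <- data.frame(cell = i,
                                 enrichmentR = cells[[i]]$truth$enrichmentR,
                                 cytoNpRef = cells[[i]]$truth$cytoNpRef)
  }
  truthPath <- file.path(outDir, "truth.csv")
  utils::write.csv(do.call(rbind, truthRows), truthPath, row.names = FALSE)
  .logLine(logPath, "simulated ", n, " '", preset, "' cells")
  c(files, truthPath)
}

.cmdRatio <- function(args, outDir, config, logPath) {
  inputDir <- args$inputDir %||% stop("ratio: missing inputDir")
  imgs <- sort(list.files(inputDir, pattern = "^cell_[0-9]+\\.tif$",
                          full.names = TRUE))
  if (length(imgs) == 0L) stop("no cell TIFFs found in ", inputDir)
  rows <- list(); nuRows <- list()
  for (i in seq_along(imgs)) {
    img <- readImage(imgs[i], pixelSize = config$pixelSizeNm)
    rois <- tiff::readTIFF(sub("\\.tif$", "_rois.tif", imgs[i]), all = TRUE)
    q <- quantifyCell(img, nucleusRoi = rois[[3]] > 0.5,
                      cytoplasmRoi = rois[[2]] > 0.5,
                      backgroundRoi = rois[[1]] > 0.5, config = config)
    rows[[i]] <- data.frame(cell = i, cytoNpRaw = q$cyto$raw,
                            cytoNpNorm = q$cyto$normalized,
                            rawRatio = q$raw$cell %||% NA_real_,
                            adjustedRatio = q$adjusted, slope = q$slope)
    if (nrow(q$raw$perNucleolus)) nuRows[[i]] <- cbind(cell = i,
                                                       q$raw$perNucleolus)
  }
  cellsDf <- do.call(rbind, rows)
  ratioPath <- file.path(outDir, "ratios.csv")
  utils::write.csv(cellsDf, ratioPath, row.names = FALSE)
  nuPath <- file.path(outDir, "nucleoli.csv")
  utils::write.csv(if (length(nuRows)) do.call(rbind, nuRows) else
                     data.frame(), nuPath, row.names = FALSE)
  popPath <- file.path(outDir, "population.json")
  jsonlite::write_json(list(
    adjustedRatio = populationSummary(cellsDf$adjustedRatio),
    cytoNpNorm = populationSummary(cellsDf$cytoNpNorm)),
    popPath, auto_unbox = TRUE, digits = NA)
  .logLine(logPath, "quantified ", nrow(cellsDf), " cells")
  c(ratioPath, nuPath, popPath)
}

.cmdColoc <- function(args, outDir, config, logPath) {
  imgPath <- args$image %||% stop("coloc: missing image")
  pair <- strsplit(args$pair %||% "marker,construct", ",")[[1]]
  mode <- args$mode %||% "control"
  img <- readImage(imgPath, pixelSize = config$pixelSizeNm)
  roisPath <- sub("\\.tif$", "_rois.tif", imgPath)
  rois <- tiff::readTIFF(roisPath, all = TRUE)
  img <- subtractBackground(img, rois[[1]] > 0.5,
                            minPixels = config$minBackgroundArea)
  mk <- buildMasks(img, rois[[3]] > 0.5, config = config)
  mask <- if (mode == "control") maskLayer(mk$masks, "nucleolarLabels") > 0
          else maskLayer(mk$masks, "nucleus")
  sc <- nucleolarScatter(channel(mk$normalized, pair[1]),
                         channel(mk$normalized, pair[2]), mask, mode = mode)
  scPath <- file.path(outDir, "scatter.csv")
  utils::write.csv(sc$pairs, scPath, row.names = FALSE)
  sumPath <- file.path(outDir, "scatter_summary.json")
  jsonlite::write_json(list(pearson = sc$pearson, r2Origin = sc$r2Origin,
                            nPixels = nrow(sc$pairs), mode = mode),
                       sumPath, auto_unbox = TRUE, digits = NA)
  .logLine(logPath, "coloc ", paste(pair, collapse = " vs "), " (", mode,
           "): r = ", round(sc$pearson, 3))
  c(scPath, sumPath)
}

.cmdFcsFit <- function(args, outDir, config, logPath) {
  curve <- readACFCurve(args$acf %||% stop("fcs-fit: missing acf"))
  fixA <- if (isTRUE(args$fixA)) config$calStructureParameter
          else if (is.numeric(args$fixA)) args$fixA else NULL
  tauLower <- if (isTRUE(args$calibration)) 0 else config$tauDifLowerS
  fit <- fitACF(curve, fixA = fixA, tauDifLower = tauLower,
                tauTripUpper = config$tauTripUpperS)
  cal <- calibrationFromConfig(config)
  p <- coef(fit)
  res <- list(params = as.list(p), atBound = as.list(atBound(fit)),
              D_um2_s = toDiffusionCoefficient(p[["tauDif"]], cal),
              concentration_nM = concentration(p[["N"]], cal)$concentration_nM)
  fitPath <- file.path(outDir, "fcs_fit.json")
  jsonlite::write_json(res, fitPath, auto_unbox = TRUE, digits = NA)
  .logLine(logPath, "FCS fit: tauDif = ", signif(p[["tauDif"]] * 1e3, 4),
           " ms, D = ", signif(res$D_um2_s, 4), " um^2/s")
  fitPath
}

.cmdFrapFit <- function(args, outDir, config, logPath) {
  traces <- readFRAPTraces(args$traces %||% stop("frap-fit: missing traces"),
                           preBleachFrames =
                             as.integer(args$preBleach %||%
                                          config$preBleachFrames))
  corr <- correctScanBleach(traces)
  resid <- residualTrace(corr$traces, corr$fit)
  rec <- fitRecovery(resid)
  corrPath <- file.path(outDir, "corrected.csv")
  writeFRAPTraces(resid, corrPath)
  fitPath <- file.path(outDir, "frap_fit.json")
  jsonlite::write_json(list(
    scanBleach = as.list(coef(corr$fit)),
    recovery = as.list(coef(rec)),
    immobileFraction = rec@immobileFraction,
    singleExpFallback = rec@singleExp),
    fitPath, auto_unbox = TRUE, digits = NA)
  .logLine(logPath, "FRAP fit: tau1 = ", signif(rec@tau1, 4), " s, a1 = ",
           signif(rec@a1, 3))
  c(fitPath, corrPath)
}

.cmdReport <- function(args, outDir, config, logPath) {
  inputDir <- args$inputDir %||% stop("report: missing inputDir")
  ratios <- utils::read.csv(file.path(inputDir, "ratios.csv"))
  rep <- lapply(ratios[setdiff(names(ratios), "cell")], function(col)
    tryCatch(populationSummary(col), error = function(e) NULL))
  repPath <- file.path(outDir, "report.json")
  jsonlite::write_json(Filter(Negate(is.null), rep), repPath,
                       auto_unbox = TRUE, digits = NA)
  .logLine(logPath, "report written for ", nrow(ratios), " cells")
  repPath
}

`%||%` <- function(a, b) if (is.null(a)) b else a
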