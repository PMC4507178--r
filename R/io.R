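# TIFF and CSV I/O. Images travel as multi-page 32-bit float TIFF (one page
# per channel or per frame) with a sidecar CSV of ground truth when written
# by the generator.

#' Read a multi-channel TIFF
#'
#' Maps TIFF pages to channels by the declared role order.
#'
#' @param path TIFF file with one page per channel.
#' @param channels character vector of channel roles in page order
#'   (default `c("marker", "reference", "construct")`).
#' @param pixelSize pixel size in nm; required (TIFF resolution tags are
#'   not relied upon).
#' @return a [MultiChannelImage-class].
#' @export
readImage <- function(path, channels = c("marker", "reference", "construct"),
                      pixelSize = NULL) {
  if (is.null(pixelSize))
    stop("pixelSize is not set; pass pixelSize= or set pixelSizeNm ",
         "in the analysis config")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * 65536                     # fixed-point convention, see writeImage()
  })
  if (length(pages) != length(channels))
    stop("file has ", length(pages), " page(s) but ", length(channels),
         " channel role(s) were declared")
  names(pages) <- channels
  MultiChannelImage(pages, pixelSize = pixelSize)
}

#' Write a MultiChannelImage (or frame list) as multi-page TIFF
#'
#' Intensities are stored as 32-bit samples under a fixed-point convention:
#' values are divided by 65536 (the 16-bit acquisition range) on write and
#' rescaled on read, giving a worst-case quantization step of about 1.5e-5
#' intensity units. Values must lie in [0, 65536).
#'
#' @param x a [MultiChannelImage-class] or a list of matrices (frames).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeImage <- function(x, path) {
  pages <- if (is(x, "MultiChannelImage")) x@channels else x
  pages <- lapply(pages, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"
    if (any(m < 0) || any(m >= 65536))
      stop("intensities must lie in [0, 65536) for TIFF storage")
    m / 65536
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read/write FCS curves and FRAP traces as CSV
#'
#' Curves use columns `lag_s`, `G`, `sd`; traces use `t_s`, `roi`,
#' `compartment`, `background`.
#'
#' @param path CSV file.
#' @return `readACFCurve`: data.frame `lag`, `G`, `sd`.
#' @export
readACFCurve <- function(path) {
  d <- utils::read.csv(path)
  need <- c("lag_s", "G")
  if (!all(need %in% names(d))) stop("curve CSV needs columns lag_s, G")
  data.frame(lag = d$lag_s, G = d$G,
             sd = if ("sd" %in% names(d)) d$sd else NA_real_)
}

#' @rdname readACFCurve
#' @param curve data.frame with `lag`, `G` and optionally `sd`.
#' @export
writeACFCurve <- function(curve, path) {
  utils::write.csv(data.frame(lag_s = curve$lag, G = curve$G,
                              sd = if (is.null(curve$sd)) NA else curve$sd),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname readACFCurve
#' @param preBleachFrames,bleachFrame frame bookkeeping for traces.
#' @export
readFRAPTraces <- function(path, preBleachFrames = 30L,
                           bleachFrame = preBleachFrames + 1L) {
  d <- utils::read.csv(path)
  need <- c("t_s", "roi", "compartment")
  if (!all(need %in% names(d)))
    stop("trace CSV needs columns t_s, roi, compartment")
  FRAPTraces(time = d$t_s, roi = d$roi, compartment = d$compartment,
             background = if ("background" %in% names(d)) d$background else 0,
             bleachFrame = bleachFrame, preBleachFrames = preBleachFrames)
}

#' @rdname readACFCurve
#' @param traces a [FRAPTraces-class].
#' @export
writeFRAPTraces <- function(traces, path) {
  bg <- traces@background
  if (length(bg) == 1L) bg <- rep(bg, length(traces@time))
  utils::write.csv(data.frame(t_s = traces@time, roi = traces@roi,
                              compartment = traces@compartment,
                              background = bg),
                   path, row.names = FALSE)
  invisible(path)
}
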