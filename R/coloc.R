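# Pixel-level co-localization of nucleolar regions: smoothed scatter plots
# with a linearity score, and line intensity profiles.

#' Smoothed scatter of paired nucleolar pixel intensities
#'
#' Pairs pixel intensities of two normalized channels (nucleoplasm = 1 in
#' both) at identical coordinates. In `control` mode the pixels come from
#' the refined nucleolar mask; in `drb` mode (disrupted nucleoli) all
#' nucleus pixels with intensity above the nucleoplasm level (> 1) in both
#' channels are used. The scatter is smoothed with a 2-D Gaussian kernel
#' density (Silverman bandwidth). Linearity is scored by the Pearson
#' correlation of the pairs plus the R-squared of the through-origin fit.
#'
#' @param imageA,imageB normalized intensity matrices.
#' @param mask logical matrix: refined nucleolar mask (`control`) or
#'   nucleus mask (`drb`).
#' @param mode `"control"` or `"drb"`.
#' @param gridSize density grid resolution.
#' @param minPixels minimum number of qualifying pixels.
#' @return list with `pairs` (data.frame `x`, `y`), `density`
#'   (from [MASS::kde2d()]), `pearson`, `r2Origin`, `mode`.
#' @export
nucleolarScatter <- function(imageA, imageB, mask,
                             mode = c("control", "drb"),
                             gridSize = 64L, minPixels = 30L) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(imageA), dim(imageB)),
            identical(dim(imageA), dim(mask)))
  sel <- if (mode == "control") mask else mask & imageA > 1 & imageB > 1
  n <- sum(sel)
  if (n < minPixels)
    stop("only ", n, " qualifying pixels (need ", minPixels, ")",
         if (mode == "drb") "; no pixels above the nucleoplasm level" else "")
  x <- imageA[sel]; y <- imageB[sel]
  bw <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  bw[bw <= 0] <- diff(range(x, y)) / 10 + 1e-6
  dens <- MASS::kde2d(x, y, h = bw, n = gridSize)
  slope <- sum(x * y) / sum(x^2)
  ssRes <- sum((y - slope * x)^2)
  ssTot <- sum(y^2)
  list(pairs = data.frame(x = x, y = y), density = dens,
       pearson = stats::cor(x, y), r2Origin = 1 - ssRes / ssTot,
       mode = mode)
}

#' Intensity profile along a line
#'
#' Samples one or more channels along the segment from `p0` to `p1`
#' (0-based pixel coordinates, (row, col)) with bilinear interpolation.
#'
#' @param image a [MultiChannelImage-class] or a single matrix.
#' @param p0,p1 segment endpoints, 0-based (row, col); must lie inside the
#'   image.
#' @param nSamples number of samples along the segment.
#' @param pixelSize nm per px (taken from the image when available).
#' @return data.frame with `position` (nm along the line) and one column
#'   per channel.
#' @export
lineProfile <- function(image, p0, p1, nSamples = 100L, pixelSize = NULL) {
  if (is(image, "MultiChannelImage")) {
    channels <- image@channels
    if (is.null(pixelSize)) pixelSize <- image@pixelSize
  } else {
    channels <- list(intensity = image)
    if (is.null(pixelSize)) pixelSize <- 1
  }
  d <- dim(channels[[1]])
  inImage <- function(p) all(p >= 0) && p[1] <= d[1] - 1 && p[2] <= d[2] - 1
  if (!inImage(p0) || !inImage(p1)) stop("endpoints must lie inside the image")
  lenPx <- sqrt(sum((p1 - p0)^2))
  if (lenPx == 0) stop("degenerate zero-length line")
  t <- seq(0, 1, length.out = nSamples)
  rows <- p0[1] + t * (p1[1] - p0[1])
  cols <- p0[2] + t * (p1[2] - p0[2])
  out <- data.frame(position = t * lenPx * pixelSize)
  for (nm in names(channels)) out[[nm]] <- bilinear(channels[[nm]], rows, cols)
  out
}
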