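# Small numerical helpers shared across the pipelines.

#' Boxcar (moving-average) smoothing with reflect padding
#'
#' Reflect padding avoids the bias a truncated window would introduce at the
#' ends of a column profile.
#'
#' @param x numeric vector.
#' @param width odd integer window width.
#' @return smoothed vector, same length as `x`.
#' @keywords internal
boxcarSmooth <- function(x, width = 11L) {
  width <- as.integer(width)
  stopifnot(width >= 1L, width %% 2L == 1L)
  if (width == 1L || length(x) == 1L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  h <- min(h, n - 1L)
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  as.numeric(stats::filter(padded, rep(1 / (2 * h + 1), 2 * h + 1),
                           sides = 2))[(h + 1L):(h + n)]
}

#' Histogram mode of a continuous sample
#'
#' The mode is taken as the centre of the fullest histogram bin, with the bin
#' width a fixed fraction of the sample range. Falls back to the median (with
#' a warning) when the histogram is degenerate, e.g. a flat image.
#'
#' @param x numeric vector.
#' @param binFraction bin width as a fraction of `diff(range(x))`.
#' @keywords internal
histogramMode <- function(x, binFraction = 0.01) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0 || length(x) < 10L) {
    warning("mode undefined (flat or tiny sample); falling back to median")
    return(stats::median(x))
  }
  bw <- diff(r) * binFraction
  breaks <- seq(r[1], r[2] + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' 2-D convolution with a small kernel and reflect padding
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @keywords internal
convolve2d <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c((kr + 1L):2L, seq_len(nr), (nr - 1L):(nr - kr))
  ci <- c((kc + 1L):2L, seq_len(nc), (nc - 1L):(nc - kc))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      out <- out + kernel[i, j] * pad[i:(i + nr - 1L), j:(j + nc - 1L)]
    }
  }
  out
}

#' Gaussian kernel of fixed support
#' @param size kernel side length in pixels (odd).
#' @param sigma standard deviation in pixels.
#' @keywords internal
gaussianKernel <- function(size = 7L, sigma = 1) {
  half <- (size - 1) / 2
  d <- seq(-half, half)
  k <- outer(exp(-d^2 / (2 * sigma^2)), exp(-d^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Mean with a Student-t 95% confidence interval
#'
#' @param x numeric vector of per-cell (or per-measurement) values.
#' @param conf confidence level.
#' @return list with `mean`, `ciLow`, `ciHigh`, `ciHalfWidth`, `n`,
#'   and `ciDefined` (FALSE when n < 2).
#' @export
populationSummary <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) stop("no finite values")
  m <- mean(x)
  if (n < 2L) {
    return(list(mean = m, ciLow = NA_real_, ciHigh = NA_real_,
                ciHalfWidth = NA_real_, n = n, ciDefined = FALSE))
  }
  hw <- stats::qt(1 - (1 - conf) / 2, df = n - 1L) * stats::sd(x) / sqrt(n)
  list(mean = m, ciLow = m - hw, ciHigh = m + hw,
       ciHalfWidth = hw, n = n, ciDefined = TRUE)
}

# Bounded Levenberg-Marquardt least squares on a residual function.
# Thin wrapper over minpack.lm::nls.lm that also extracts approximate
# standard errors from the final Jacobian (NA when it is rank-deficient).
.lmFit <- function(par, lower, upper, residFn, maxiter = 500) {
  out <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = residFn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  conv <- out$info %in% 1:4
  se <- rep(NA_real_, length(par))
  names(se) <- names(par)
  covm <- tryCatch({
    dof <- max(length(out$fvec) - length(par), 1L)
    solve(out$hessian) * out$deviance / dof
  }, error = function(e) NULL)
  if (!is.null(covm)) {
    d <- diag(covm)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  list(par = out$par, se = se, deviance = out$deviance,
       converged = conv, message = out$message)
}

# Binary erosion of a logical mask by a disc of the given pixel radius,
# via shifted ANDs; used as the partial-volume guard on refined nucleolar
# masks before ratio estimation.
binaryErode <- function(mask, radius) {
  radius <- as.integer(radius)
  if (radius <= 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr * dr + dc * dc > radius * radius) next
    shifted <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs - dr, cs - dc] <- mask[rs, cs]
    out <- out & shifted
  }
  out
}

# Bilinear interpolation of matrix `img` at fractional 0-based (row, col)
# coordinates; clamps to the image border.
bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(row), nr - 2); c0 <- pmin(floor(col), nc - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- row - r0; fc <- col - c0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c0 + 2)]
  i11 <- img[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}
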