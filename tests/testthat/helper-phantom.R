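# Shared fixture builders. Everything is generated in code at test time.

# A compact cell phantom that runs the full mask pipeline quickly.
smallPhantom <- function(enrichmentR = 2.46, noise = NULL, seed = 7, ...) {
  args <- list(imageSize = c(256L, 256L), nucleusAxes = c(48, 60),
               cellAxes = c(80, 105), nNucleoli = 3L,
               nucleolusRadii = c(13, 10, 8), enrichmentR = enrichmentR,
               cytoNpRef = 0.89, cytoNpConstructNorm = 0.2, seed = seed)
  if (!is.null(noise)) {
    args$noise <- noise
    if (identical(noise, "off")) {
      args$shadingAmplitude <- 0
      args$offset <- 0
    }
  }
  do.call(cellPhantomSpec, utils::modifyList(args, list(...)))
}

quietConfig <- function(...) analysisConfig(..., quiet = TRUE)

# Truth-ROI quantification of one rendered phantom.
quantifyPhantom <- function(ph, config = quietConfig()) {
  tm <- ph$truth$masks
  quantifyCell(ph$image, nucleusRoi = maskLayer(tm, "nucleus"),
               cytoplasmRoi = maskLayer(tm, "cytoplasm"),
               backgroundRoi = maskLayer(tm, "background"), config = config)
}

iou <- function(a, b) sum(a & b) / sum(a | b)
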