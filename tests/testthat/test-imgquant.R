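# Mask pipeline, ratio estimators and population statistics.

test_that("background subtraction removes a constant offset and clips at zero", {
  m <- matrix(100, 64, 64)
  img <- MultiChannelImage(list(marker = m, reference = m, construct = m))
  roi <- matrix(FALSE, 64, 64); roi[1:10, 1:10] <- TRUE
  out <- subtractBackground(img, roi)
  expect_true(all(channel(out, "marker") == 0))
  # offset on structured data leaves the signal intact
  ph <- makeCellImage(smallPhantom(noise = "off", offset = 0))
  img2 <- ph$image
  img2@channels <- lapply(img2@channels, `+`, 100)
  rec <- subtractBackground(img2, maskLayer(ph$truth$masks, "background"))
  expect_equal(channel(rec, "construct"), channel(ph$image, "construct"),
               tolerance = 1e-12)
  expect_error(subtractBackground(img, matrix(FALSE, 64, 64)), "empty")
  expect_error(subtractBackground(img, roi[1:10, 1:10]), "dimensions")
})

test_that("cytoplasm/nucleoplasm ratio normalizes a reference-like construct to one", {
  ph <- makeCellImage(smallPhantom(seed = 2))
  tm <- ph$truth$masks
  img <- ph$image
  # construct identical to reference: normalized ratio is exactly 1
  img@channels$construct <- img@channels$reference
  r <- cytoNpRatio(img, maskLayer(tm, "cytoplasm"),
                   maskLayer(tm, "nucleoplasm"))
  expect_identical(r$normalized, 1)
  zeroImg <- MultiChannelImage(list(reference = matrix(0, 8, 8),
                                    construct = matrix(1, 8, 8)))
  expect_error(cytoNpRatio(zeroImg, matrix(TRUE, 8, 8), matrix(TRUE, 8, 8)),
               "zero nucleoplasm median")
})

test_that("mask pipeline recovers nucleoli with IoU >= 0.9 on noise-free phantoms", {
  ph <- makeCellImage(smallPhantom(noise = "off", nNucleoli = 2L,
                                   nucleolusRadii = c(13, 10)))
  mk <- buildMasks(ph$image, maskLayer(ph$truth$masks, "nucleus"),
                   config = quietConfig())
  refined <- maskLayer(mk$masks, "nucleolarLabels") > 0
  truth <- maskLayer(ph$truth$masks, "nucleolarLabels") > 0
  expect_gte(iou(refined, truth), 0.9)
  expect_true(validObject(mk$masks))
  # per-nucleolus refinement recorded its half-minimum levels
  expect_length(maskProvenance(mk$masks)$fwhmLevels, 2L)
})

test_that("an image without nucleolar structure yields an empty nucleolar mask", {
  ph <- makeCellImage(smallPhantom(seed = 3, noise = "off"))
  img <- ph$image
  img@channels$marker <- img@channels$reference  # marker has no enrichment
  img@channels$construct <- img@channels$reference
  nucleus <- maskLayer(ph$truth$masks, "nucleus")
  mk <- buildMasks(img, nucleus, config = quietConfig())
  expect_equal(sum(maskLayer(mk$masks, "nucleolarLabels") > 0), 0)
  expect_identical(maskLayer(mk$masks, "nucleoplasm"), nucleus)
})

test_that("masks are invariant to a global intensity scale", {
  ph <- makeCellImage(smallPhantom(seed = 4))
  nucleus <- maskLayer(ph$truth$masks, "nucleus")
  mk1 <- buildMasks(ph$image, nucleus, config = quietConfig())
  scaled <- ph$image
  scaled@channels <- lapply(scaled@channels, `*`, 10)
  mk2 <- buildMasks(scaled, nucleus, config = quietConfig())
  expect_identical(maskLayer(mk1$masks, "nucleolarFinal"),
                   maskLayer(mk2$masks, "nucleolarFinal"))
  expect_identical(maskLayer(mk1$masks, "nucleolarLabels"),
                   maskLayer(mk2$masks, "nucleolarLabels"))
})

test_that("column shading is removed: normalized nucleoplasm median is 1", {
  ph <- makeCellImage(smallPhantom(seed = 6, shadingAmplitude = 0.15))
  mk <- buildMasks(ph$image, maskLayer(ph$truth$masks, "nucleus"),
                   config = quietConfig())
  np <- maskLayer(mk$masks, "nucleoplasm")
  for (ch in c("marker", "reference", "construct")) {
    med <- stats::median(channel(mk$normalized, ch)[np])
    expect_equal(med, 1, tolerance = 0.02)
  }
})

test_that("raw nucleolar ratios follow the accessible volume and area weighting", {
  # uniform construct (no exclusion anywhere) scores exactly 1
  labs <- matrix(0L, 32, 32); labs[5:10, 5:10] <- 1L
  masks <- new("MaskSet", background = matrix(FALSE, 32, 32),
               cytoplasm = matrix(FALSE, 32, 32),
               nucleus = matrix(TRUE, 32, 32),
               nucleolarInitial = labs > 0, nucleolarFinal = labs > 0,
               nucleolarLabels = labs,
               nucleoplasm = matrix(TRUE, 32, 32) & !(labs > 0),
               provenance = list())
  uni <- MultiChannelImage(list(construct = matrix(1, 32, 32),
                                reference = matrix(1, 32, 32)))
  expect_equal(rawNucleolarRatio(uni, masks)$cell, 1.0)
  # hand-computed area weighting: areas 100/300 with ratios 1/2 -> 1.75
  labs2 <- matrix(0L, 40, 40)
  labs2[1:10, 1:10] <- 1L          # 100 px
  labs2[21:35, 21:40] <- 2L        # 300 px
  m <- matrix(1, 40, 40); m[labs2 == 2L] <- 2
  masks2 <- new("MaskSet", background = matrix(FALSE, 40, 40),
                cytoplasm = matrix(FALSE, 40, 40),
                nucleus = matrix(TRUE, 40, 40),
                nucleolarInitial = labs2 > 0, nucleolarFinal = labs2 > 0,
                nucleolarLabels = labs2,
                nucleoplasm = matrix(TRUE, 40, 40) & !(labs2 > 0),
                provenance = list())
  img2 <- MultiChannelImage(list(construct = m))
  expect_equal(rawNucleolarRatio(img2, masks2)$cell, 1.75)
  # reference-like construct in an f = 0.5 phantom scores about 0.5
  ph <- makeCellImage(smallPhantom(noise = "off", enrichmentR = 0,
                                   cytoNpConstructNorm = 1))
  mk <- buildMasks(ph$image, maskLayer(ph$truth$masks, "nucleus"),
                   config = quietConfig())
  r <- rawNucleolarRatio(mk$normalized, mk$masks)
  expect_equal(r$cell, 0.5, tolerance = 0.1)
})

test_that("adjusted ratio equals the closed-form through-origin slope minus one", {
  f <- c(0.4, 0.5, 0.6)
  expect_equal(adjustedRatio(3.46 * f, f, minPixels = 3L)$adjusted, 2.46,
               tolerance = 1e-12)
  expect_equal(adjustedRatio(f, f, minPixels = 3L)$adjusted, 0,
               tolerance = 1e-12)
  expect_error(adjustedRatio(f, rep(0, 3), minPixels = 3L), "accessible")
  expect_error(adjustedRatio(f, f[1:2], minPixels = 2L), "equal length")
})

test_that("adjusted ratio matches brute-force least squares on random vectors", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    f <- stats::runif(n, 0.05, 1.4)
    F <- stats::runif(n, 0, 3)
    slope <- adjustedRatio(F, f)$slope
    brute <- stats::optimize(function(b) sum((F - b * f)^2),
                             c(-10, 10), tol = 1e-12)$minimum
    expect_equal(slope, brute, tolerance = 1e-9)
  }
})

test_that("population summary gives exact t-based intervals", {
  s <- populationSummary(c(1, 1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$ciHalfWidth, 0)
  s2 <- populationSummary(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$ciHalfWidth, stats::qt(0.975, 1) * stats::sd(c(0, 2)) /
                 sqrt(2), tolerance = 1e-12)
  s1 <- populationSummary(5)
  expect_false(s1$ciDefined)
})

test_that("noise-free phantoms are recovered exactly from truth-core pixels", {
  for (R in c(0.27, 0.9, 2.46)) {
    ph <- makeCellImage(smallPhantom(enrichmentR = R, noise = "off"))
    tm <- ph$truth$masks
    ref <- channel(ph$image, "reference")
    con <- channel(ph$image, "construct")
    np <- maskLayer(tm, "nucleoplasm") & ph$truth$nucleolusProfile == 0
    core <- ph$truth$coreLabels > 0
    est <- adjustedRatio(con[core] / stats::median(con[np]),
                         ref[core] / stats::median(ref[np]))
    expect_equal(est$adjusted, R, tolerance = 1e-6)
    cy <- cytoNpRatio(ph$image, maskLayer(tm, "cytoplasm"), np,
                      channel = "reference")
    expect_equal(cy$raw, 0.89, tolerance = 1e-6)
  }
})

test_that("estimated adjusted ratio increases strictly with true enrichment", {
  ests <- vapply(c(0.3, 0.9, 1.6, 2.46), function(R) {
    ph <- makeCellImage(smallPhantom(enrichmentR = R, seed = 21))
    quantifyPhantom(ph)$adjusted
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("preset populations recover truth within their own confidence interval", {
  for (preset in c("SNAILA-FL", "HsSNAIL2")) {
    truthR <- presetTable("cell", preset)$enrichmentR
    rs <- quantifyPopulation(simulateCells(preset, n = 8, seed = 31),
                             config = quietConfig())
    p <- populationStats(rs)$adjustedRatio
    expect_lt(abs(p$mean - truthR), max(p$ciHalfWidth, 0.25))
  }
})
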