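# Co-localization scatter and line profiles.

test_that("proportional channels score perfect linearity", {
  set.seed(1)
  A <- matrix(stats::runif(400, 0.5, 3), 20, 20)
  B <- 2 * A
  mask <- matrix(TRUE, 20, 20)
  sc <- nucleolarScatter(A, B, mask)
  expect_equal(sc$pearson, 1, tolerance = 1e-12)
  expect_equal(sc$r2Origin, 1, tolerance = 1e-12)
  expect_equal(nrow(sc$pairs), 400L)
})

test_that("linearity score is symmetric and affine invariant", {
  set.seed(2)
  A <- matrix(stats::rlnorm(900), 30, 30)
  B <- matrix(A + stats::rnorm(900, 0, 0.3), 30, 30)
  mask <- matrix(TRUE, 30, 30)
  r1 <- nucleolarScatter(A, B, mask)$pearson
  r2 <- nucleolarScatter(B, A, mask)$pearson
  expect_equal(r1, r2, tolerance = 1e-12)
  r3 <- nucleolarScatter(1.7 * A + 0.2, B, mask)$pearson
  expect_equal(r1, r3, tolerance = 1e-9)
})

test_that("disrupted-nucleolus mode keeps only pixels above the nucleoplasm level", {
  set.seed(3)
  A <- matrix(stats::runif(2500, 0.2, 2.2), 50, 50)
  B <- matrix(stats::runif(2500, 0.2, 2.2), 50, 50)
  mask <- matrix(TRUE, 50, 50)
  sc <- nucleolarScatter(A, B, mask, mode = "drb")
  expect_true(all(sc$pairs$x > 1 & sc$pairs$y > 1))
  uni <- matrix(1, 50, 50)
  expect_error(nucleolarScatter(uni, uni, mask, mode = "drb"),
               "qualifying pixels")
})

test_that("two-zone marker is less linear against the construct than a one-zone marker", {
  # same geometry and seed; second phantom renders the marker without the
  # inner bright zone, i.e. a purely granular-component-like marker
  twoZone <- makeCellImage(smallPhantom(seed = 12, nNucleoli = 2L,
                                        nucleolusRadii = c(14, 12)))
  oneZone <- makeCellImage(smallPhantom(seed = 12, nNucleoli = 2L,
                                        nucleolusRadii = c(14, 12),
                                        markerDFC = 3))  # = markerGC
  nucleus <- maskLayer(twoZone$truth$masks, "nucleus")
  mk2 <- buildMasks(twoZone$image, nucleus, config = quietConfig())
  mk1 <- buildMasks(oneZone$image, nucleus, config = quietConfig())
  mask <- maskLayer(mk2$masks, "nucleolarLabels") > 0
  con <- channel(mk2$normalized, "construct")
  rTwo <- nucleolarScatter(channel(mk2$normalized, "marker"), con,
                           mask)$pearson
  rOne <- nucleolarScatter(channel(mk1$normalized, "marker"), con,
                           mask)$pearson
  expect_lt(rTwo, rOne)
})

test_that("disrupted-nucleolus phantoms feed the drb scatter mode", {
  ph <- makeCellImage(smallPhantom(seed = 15, fragmented = TRUE,
                                   enrichmentR = 1.2))
  mk <- buildMasks(ph$image, maskLayer(ph$truth$masks, "nucleus"),
                   config = quietConfig())
  sc <- nucleolarScatter(channel(mk$normalized, "marker"),
                         channel(mk$normalized, "construct"),
                         maskLayer(mk$masks, "nucleus"), mode = "drb")
  expect_gte(nrow(sc$pairs), 30L)
  expect_true(all(sc$pairs$x > 1 & sc$pairs$y > 1))
  expect_true(is.finite(sc$pearson))
})

test_that("line profiles interpolate analytic structures correctly", {
  # constant image -> flat profile
  img <- matrix(3.5, 64, 64)
  lp <- lineProfile(img, c(10, 5), c(50, 60), nSamples = 50)
  expect_lt(diff(range(lp$intensity)), 1e-12)
  # horizontal cut through a soft disk matches the generative cross-section
  ph <- makeCellImage(smallPhantom(noise = "off", nNucleoli = 1L,
                                   nucleolusRadii = 12))
  ctr <- ph$truth$nucleolusCenters[1, ]
  prof <- lineProfile(ph$image, ctr - c(0, 25), ctr + c(0, 25),
                      nSamples = 101)
  d <- abs(seq(-25, 25, length.out = 101))
  expected <- 100 * (1 - 0.5 * stats::pnorm((12 - d) / 1))
  expect_equal(prof$reference, expected, tolerance = 0.02)
  expect_error(lineProfile(ph$image, ctr, ctr), "zero-length")
  expect_error(lineProfile(ph$image, c(-5, 0), ctr), "inside the image")
})

test_that("construct and granular marker profiles overlap while the dense zone peaks apart", {
  ph <- makeCellImage(smallPhantom(noise = "off", nNucleoli = 1L,
                                   nucleolusRadii = 14))
  ctr <- ph$truth$nucleolusCenters[1, ]
  prof <- lineProfile(ph$image, ctr - c(0, 20), ctr + c(0, 20),
                      nSamples = 81)
  inner <- abs(seq(-20, 20, length.out = 81)) < 8
  # marker keeps rising into the dense inner zone; construct plateaus
  conRange <- diff(range(prof$construct[inner])) / max(prof$construct)
  mrkRange <- diff(range(prof$marker[inner])) / max(prof$marker)
  expect_lt(conRange, 0.05)
  expect_gt(mrkRange, 0.2)
})
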