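# Autocorrelation model, multiple-tau estimator, bounded fitting and
# calibration conversions.

calParams <- list(N = 10, T = 0.15, tauTrip = 30e-6, tauDif = 0.14e-3, a = 8)

test_that("model values match direct evaluation", {
  expect_equal(modelACF(1e-3, list(N = 1, T = 0, tauTrip = 1e-5,
                                   tauDif = 1e-3, a = 8)),
               0.5 * (1 + 1 / 64)^-0.5, tolerance = 1e-12)
  expect_equal(modelACF(1e-9, list(N = 4, T = 0, tauTrip = 1e-5,
                                   tauDif = 1e-3, a = 8)),
               0.25, tolerance = 1e-5)
  expect_lt(modelACF(1e4, calParams), 1e-6)
  expect_error(modelACF(c(-1, 1e-3), calParams), "positive")
  expect_error(modelACF(1e-3, list(N = 1, T = 1, tauTrip = 1e-5,
                                   tauDif = 1e-3, a = 8)), "T")
})

test_that("model is strictly decreasing in lag without a dark state", {
  lag <- 10^seq(-6, 1, length.out = 200)
  for (p in list(list(N = 2, T = 0, tauTrip = 1e-5, tauDif = 5e-4, a = 3),
                 list(N = 50, T = 0, tauTrip = 1e-5, tauDif = 2e-2, a = 8))) {
    expect_true(all(diff(modelACF(lag, p)) < 0))
  }
})

test_that("multiple-tau ACF of pure shot noise is flat at zero", {
  set.seed(8)
  x <- stats::rpois(2e4, 20)
  ac <- autocorrelate(x, binWidth = 1e-4)
  expect_lt(max(abs(ac$G)), 0.01)
})

test_that("ACF is stationary: duplicating the trace barely changes it", {
  set.seed(9)
  n <- 2e4
  x <- 5 + as.numeric(stats::arima.sim(list(ar = 0.95), n)) # correlated trace
  x <- pmax(x, 0)
  a1 <- autocorrelate(x, binWidth = 1e-4)
  a2 <- autocorrelate(c(x, x), binWidth = 1e-4)
  shared <- seq_len(nrow(a1))
  expect_lt(max(abs(a2$G[shared] - a1$G[shared])), 0.05 * max(a1$G))
  expect_error(autocorrelate(x[1:100], binWidth = 1e-4), "bins")
})

test_that("segment quality control rejects bleached stretches", {
  set.seed(10)
  good <- stats::rpois(2e4, 50)
  bad <- c(stats::rpois(1.8e4, 50), stats::rpois(2e3, 5)) # end-spike drop
  acGood <- autocorrelate(good, binWidth = 1e-4)
  acBad <- autocorrelate(bad, binWidth = 1e-4)
  expect_equal(acBad$G, acGood$G, tolerance = 0.02) # dropped, not averaged in
  expect_error(autocorrelate(rep(0:1, 1e4) * c(rep(1e6, 1e4), rep(1, 1e4)),
                             binWidth = 1e-4, segmentTolerance = 1e-9),
               "all segments rejected")
})

test_that("fit on noiseless model output is an exact fixed point", {
  p <- list(N = 5, T = 0.1, tauTrip = 50e-6, tauDif = 1e-3, a = 8)
  sim <- makeACF(fcsSimSpec(params = p, noiseSdRel = 0, seed = 1))
  fit <- fitACF(sim$curve, tauDifLower = 0)
  est <- coef(fit)
  for (nm in names(est))
    expect_equal(est[[nm]], p[[nm]], tolerance = 1e-6)
  expect_false(any(atBound(fit)))
})

test_that("calibration curve recovery returns the reference diffusion time and geometry", {
  sim <- makeACF(fcsSimSpec(params = calParams, noiseSdRel = 0.02,
                            nLags = 50, seed = 3))
  free <- fitACF(sim$curve, tauDifLower = 0)
  expect_equal(coef(free)[["tauDif"]], 0.14e-3, tolerance = 0.1)
  expect_equal(coef(free)[["a"]], 8, tolerance = 0.15)
  fixed <- fitACF(sim$curve, fixA = 8, tauDifLower = 0)
  expect_equal(coef(fixed)[["tauDif"]], 0.14e-3, tolerance = 0.05)
})

test_that("a diffusion time below the cellular bound is pinned and flagged", {
  p <- list(N = 5, T = 0.1, tauTrip = 30e-6, tauDif = 1e-4, a = 8)
  sim <- makeACF(fcsSimSpec(params = p, noiseSdRel = 0.01, nLags = 40,
                            seed = 5))
  fit <- fitACF(sim$curve, fixA = 8)   # default bounds: tauDif >= 200 us
  expect_equal(coef(fit)[["tauDif"]], 200e-6, tolerance = 1e-6)
  expect_true(atBound(fit)[["tauDif"]])
})

test_that("diffusion-time calibration conversion is the inverse proportionality", {
  expect_equal(toDiffusionCoefficient(0.14e-3), 90, tolerance = 1e-12)
  expect_equal(toDiffusionCoefficient(0.548e-3), 23, tolerance = 0.015)
  cal <- FCSCalibration()
  expect_equal(toDiffusionCoefficient(2 * cal@tauRef, cal), cal@DRef / 2,
               tolerance = 1e-12)
  expect_error(toDiffusionCoefficient(-1e-3), "positive")
})

test_that("effective volume and concentration reproduce the calibration arithmetic", {
  cc <- concentration(61)
  expect_equal(cc$volume_fL, 8 * (4 * pi * 90 * 1.4e-4)^1.5,
               tolerance = 1e-12)
  expect_equal(cc$volume_fL, 0.504, tolerance = 0.001)
  expect_equal(cc$concentration_nM, 201, tolerance = 0.005)
  expect_equal(concentration(122)$concentration_nM,
               2 * cc$concentration_nM, tolerance = 1e-12)
})

test_that("diffusion-time recovery at 2% curve noise has median error below 5%", {
  errs <- vapply(1:100, function(i) {
    p <- list(N = 20, T = 0.15, tauTrip = 40e-6, tauDif = 2e-3, a = 8)
    sim <- makeACF(fcsSimSpec(params = p, noiseSdRel = 0.02, nLags = 50,
                              seed = 1000 + i))
    fit <- fitACF(sim$curve, fixA = 8, tauDifLower = 0)
    abs(coef(fit)[["tauDif"]] - p$tauDif) / p$tauDif
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("diffusion coefficients recovered end to end preserve the preset ordering", {
  cal <- FCSCalibration()
  Dhat <- vapply(c("dZnf-nucleoplasm", "FL-nucleoplasm", "FL-nucleolus"),
                 function(ps) {
    sim <- makeACF(fcsSimSpec(params = ps, noiseSdRel = 0.02, nLags = 50,
                              seed = 77))
    toDiffusionCoefficient(coef(fitACF(sim$curve, fixA = 8))[["tauDif"]],
                           cal)
  }, numeric(1))
  expect_true(all(diff(Dhat) < 0))
  truthD <- vapply(c("dZnf-nucleoplasm", "FL-nucleoplasm", "FL-nucleolus"),
                   function(ps)
                     toDiffusionCoefficient(presetTable("fcs", ps)$tauDif,
                                            cal), numeric(1))
  expect_equal(unname(Dhat), unname(truthD), tolerance = 0.1)
})

test_that("brownian-trace chain recovers the simulated diffusion time within 10%", {
  p <- list(N = 5, T = 0, tauTrip = 1e-5, tauDif = 2e-3, a = 6)
  sim <- makeACF(fcsSimSpec(mode = "brownian-trace", params = p,
                            duration = 30, binWidth = 1e-4, seed = 6))
  ac <- autocorrelate(sim, nSegments = 5L)
  fit <- fitACF(ac[ac$lag <= 0.15, ], fixA = 6, tauDifLower = 0,
                tauTripUpper = 1.5e-4)
  expect_equal(coef(fit)[["tauDif"]], p$tauDif, tolerance = 0.1)
  expect_equal(coef(fit)[["N"]], p$N, tolerance = 0.1)
})
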