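# FRAP correction chain, recovery fitting and radial profiles.

nucleolusTraces <- function(n = 6, noiseSd = 0.02, base = 100) {
  lapply(seq_len(n), function(i)
    makeFRAP(frapSimSpec(mode = "trace", recovery = "nucleolus",
                         noiseSd = noiseSd, seed = base + i)))
}

correctAll <- function(sims) {
  lapply(sims, function(x) {
    c <- correctScanBleach(x$traces)
    residualTrace(c$traces, c$fit)
  })
}

test_that("correction is the identity on clean, decay-free traces", {
  flat <- makeFRAP(frapSimSpec(
    mode = "trace",
    recovery = list(a1 = 0, tau1 = 1, a2 = 0, tau2 = 2, stepLoss = 0,
                    bleachDepth = 0, immobileFraction = 0),
    scanBleach = list(A1 = 0, tauA = 8, A2 = 0, tauB = 60),
    noiseSd = 0, background = 0, seed = 1))
  out <- correctScanBleach(flat$traces)
  expect_lt(out$fit@step, 1e-6)
  expect_equal(out$traces@roi, rep(1, length(out$traces@roi)),
               tolerance = 1e-9)
})

test_that("known scan decay and step loss are recovered accurately", {
  sim <- makeFRAP(frapSimSpec(mode = "trace", recovery = "nucleolus",
                              noiseSd = 0.02, seed = 42))
  out <- correctScanBleach(sim$traces)
  expect_lt(abs(out$fit@step - 0.12), 0.015)
  pre <- seq_len(sim$traces@preBleachFrames)
  expect_equal(mean(out$traces@roi[pre]), 1, tolerance = 0.01)
  expect_equal(mean(out$traces@compartment[pre]), 1, tolerance = 0.01)
  expect_gt(out$fit@step, 0)  # FLIP step visible in the compartment trace
})

test_that("correction is idempotent", {
  sim <- makeFRAP(frapSimSpec(mode = "trace", recovery = "nucleoplasm",
                              noiseSd = 0.01, seed = 7))
  once <- correctScanBleach(sim$traces)
  # feed the fully corrected (step-removed) traces back in
  resid <- residualTrace(once$traces, once$fit)
  twice <- correctScanBleach(resid)
  expect_lt(twice$fit@step, 0.01)
  # the re-fitted scan decay is flat: no residual bleaching detected
  cf <- coef(twice$fit)
  t <- resid@time
  decay <- cf[["A0"]] + cf[["A1"]] * exp(-t / cf[["tauA"]]) +
    cf[["A2"]] * exp(-t / cf[["tauB"]])
  expect_lt(max(abs(decay / decay[1] - 1)), 0.01)
})

test_that("residual traces plateau at one minus the immobile fraction", {
  immobile <- makeFRAP(frapSimSpec(
    mode = "trace",
    recovery = list(a1 = 0.46, tau1 = 1.98, a2 = 0.18, tau2 = 11.12,
                    stepLoss = 0.12, bleachDepth = 0.64,
                    immobileFraction = 0.3),
    noiseSd = 0.01, seed = 3))
  c1 <- correctScanBleach(immobile$traces)
  r1 <- residualTrace(c1$traces, c1$fit)
  fit <- fitRecovery(r1)
  expect_equal(fit@immobileFraction, 0.3, tolerance = 0.07)
  # full-recovery preset: immobile fraction about zero
  full <- correctAll(nucleolusTraces(1, base = 50))[[1]]
  expect_lt(abs(fitRecovery(full)@immobileFraction), 0.05)
  expect_error(residualTrace(c1$traces, 1), "< 1")
})

test_that("residual transform with zero step is the identity", {
  sim <- makeFRAP(frapSimSpec(mode = "trace", recovery = "nucleolus",
                              noiseSd = 0, seed = 2))
  corr <- correctScanBleach(sim$traces)
  r0 <- residualTrace(corr$traces, 0)
  expect_identical(r0@roi, corr$traces@roi)
})

test_that("noiseless double-exponential traces are fitted exactly", {
  t <- seq(0, 59) * 0.331
  y <- 1 - 0.46 * exp(-t / 1.98) - 0.18 * exp(-t / 11.12)
  tr <- FRAPTraces(time = c(seq(-10, -1) * 0.331 + t[1], t) + 10,
                   roi = c(rep(1, 10), y),
                   compartment = rep(1, 70), background = 0,
                   bleachFrame = 11L, preBleachFrames = 10L)
  fit <- fitRecovery(tr, minPostBleach = 30L)
  expect_equal(fit@a1, 0.46, tolerance = 1e-6)
  expect_equal(fit@tau1, 1.98, tolerance = 1e-6)
  expect_equal(fit@a2, 0.18, tolerance = 1e-6)
  expect_equal(fit@tau2, 11.12, tolerance = 1e-6)
  expect_true(fit@tau1 <= fit@tau2)
})

test_that("averaged nucleolus-preset traces reproduce the preset recovery constants", {
  fit <- fitRecovery(correctAll(nucleolusTraces(6, base = 100)))
  expect_equal(fit@tau1, 1.98, tolerance = 0.1)
  expect_equal(fit@a1, 0.46, tolerance = 0.1)
  npFit <- fitRecovery(correctAll(lapply(1:6, function(i)
    makeFRAP(frapSimSpec(mode = "trace", recovery = "nucleoplasm",
                         noiseSd = 0.02, seed = 900 + i)))))
  expect_equal(npFit@tau1, 1.31, tolerance = 0.15)
  expect_lt(npFit@tau1, fit@tau1)  # nucleoplasm recovers faster
})

test_that("recovery-constant estimation at 2% noise has median error below 10%", {
  # one replicate = one six-trace measurement set, the unit the recovery
  # constants are reported for
  errs <- vapply(1:50, function(i) {
    fit <- fitRecovery(correctAll(nucleolusTraces(6, base = 2000 + 10 * i)))
    c(abs(fit@tau1 - 1.98) / 1.98, abs(fit@tau2 - 11.12) / 11.12)
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.1)
  expect_lt(stats::median(errs[2, ]), 0.1)
})

test_that("radial profiles are flat on uniform frames and partition the mask", {
  n <- 64
  rowc <- matrix(seq_len(n) - 1, n, n)
  colc <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  mask <- sqrt((rowc - 31.5)^2 + (colc - 31.5)^2) <= 25
  prof <- radialProfile(matrix(2, n, n), c(31.5, 31.5), mask,
                        pixelSize = 207)
  expect_true(all(abs(prof@mean[prof@n > 0] - 2) < 1e-12))
  expect_identical(sum(prof@n), sum(mask))
  expect_equal(prof@radius[1], 207 / 2)
  expect_error(radialProfile(matrix(2, n, n), c(0, 0), mask), "inside")
})

test_that("ring means of a gaussian bleach spot match the analytic profile", {
  n <- 96; sigma <- 9
  rowc <- matrix(seq_len(n) - 1, n, n)
  colc <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  ctr <- c((n - 1) / 2, (n - 1) / 2)
  r <- sqrt((rowc - ctr[1])^2 + (colc - ctr[2])^2)
  g <- 1 - 0.8 * exp(-r^2 / (2 * sigma^2))
  prof <- radialProfile(g, ctr, matrix(TRUE, n, n), pixelSize = 207)
  rPx <- prof@radius / 207
  sel <- prof@n > 0 & rPx < 30
  expected <- 1 - 0.8 * exp(-rPx[sel]^2 / (2 * sigma^2))
  expect_lt(max(abs(prof@mean[sel] - expected) / 0.8), 0.02)
})

test_that("initial radial profile steepness decreases with diffusion coefficient", {
  slopes <- vapply(c(0.35, 1.5, 3.5), function(D) {
    mv <- makeFRAP(frapSimSpec(mode = "movie", gridSize = 64L,
                               nucleusRadius = 26, nucleolusRadius = 10,
                               DMap = list(nucleoplasm = D, nucleolus = D),
                               preBleachFrames = 2L, totalFrames = 8L,
                               noiseSd = 0, seed = 4))
    prof <- radialProfile(mv$frames[[mv$bleachFrame]], mv$bleachCenter,
                          mv$nucleus, pixelSize = 207)
    ok <- which(prof@n > 0 & prof@radius < 2500)
    # depth of the bleach spot relative to the far field
    far <- mean(prof@mean[ok][prof@radius[ok] > 1800])
    far - prof@mean[ok][1]
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})
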