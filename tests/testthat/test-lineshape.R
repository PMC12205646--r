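# Lorentzian peak fitting, T2/area recovery, and build-up fitting.

test_that("a 10 Hz Lorentzian yields T2 = 31.83 ms", {
  sim <- simulateSpectrum(
    data.frame(center_ppm = -60.5, t2_ms = 1000 / (pi * 10), area = 3),
    noiseSD = 0, seed = 1)
  pk <- fitLorentzians(sim$spectrum, 1, -60.45)
  expect_equal(pk$t2_ms, 1000 / (pi * 10), tolerance = 1e-4)
  expect_equal(pk$fwhm_hz, 10, tolerance = 1e-4)
  expect_equal(pk$center_ppm, -60.5, tolerance = 1e-6)
  expect_equal(pk$area, 3, tolerance = 1e-4)
})

test_that("noise-free peak height matches the Lorentzian closed form", {
  area <- 2.4; t2 <- 64.1; field <- 657
  sim <- simulateSpectrum(
    data.frame(center_ppm = -60, t2_ms = t2, area = area),
    noiseSD = 0, fieldMHz = field, seed = 1)
  fwhmPpm <- 1000 / (pi * t2) / field
  i0 <- max(sim$spectrum@intensity)
  expect_equal(i0, 2 * area / (pi * fwhmPpm), tolerance = 1e-4)
})

test_that("two-peak area ratio and widths recover at high SNR", {
  truth <- data.frame(center_ppm = c(-60.2, -61.3),
                      t2_ms = c(64.1, 125), area = c(4, 1))
  # SNR relative to the smaller peak's height stays >= 50
  smallHeight <- 2 * 1 / (pi * (1000 / (pi * 125) / 657))
  sim <- simulateSpectrum(truth, noiseSD = smallHeight / 80, seed = 12)
  pk <- fitLorentzians(sim$spectrum, 2, c(-60.15, -61.25))
  pk <- pk[order(pk$center_ppm, decreasing = TRUE), ]
  expect_equal(pk$t2_ms, truth$t2_ms, tolerance = 0.01)
  expect_equal(pk$area[1] / pk$area[2], 4, tolerance = 0.02)
  # total area conserved within 2%
  expect_equal(sum(pk$area), sum(truth$area), tolerance = 0.02)
})

test_that("degenerate spectra and bad inits are rejected", {
  flat <- Spectrum1D(seq(-63, -58, length.out = 100), rep(0, 100))
  expect_error(fitLorentzians(flat, 1, -60), "no signal")
  sim <- simulateSpectrum(
    data.frame(center_ppm = -60, t2_ms = 60, area = 1), seed = 1)
  expect_error(fitLorentzians(sim$spectrum, 2, c(-60, -60 + 1e-9)),
               "point spacing")
  expect_error(fitLorentzians(sim$spectrum, 1, -40), "within the ppm axis")
})

test_that("a decreasing ppm axis is normalized on construction", {
  s <- Spectrum1D(c(-58, -59, -60), c(1, 2, 3))
  expect_equal(s@ppm, c(-60, -59, -58))
  expect_equal(s@intensity, c(3, 2, 1))
})

test_that("noise-free build-up recovers the shared rate exactly", {
  sim <- simulateBuildup(kObs = 1e-3, aClosedInf = 1, aNMStart = 1,
                         aNMEnd = 0.2, noiseSD = 0, seed = 1)
  fit <- fitBuildup(sim$series, nDraws = 0)
  expect_equal(fit$kObs, 1e-3, tolerance = 1e-6)
  expect_equal(fit$aClosedInf, 1, tolerance = 1e-6)
  expect_equal(fit$aNMEnd, 0.2, tolerance = 1e-6)
  expect_true(fit$buildupDetected)
})

test_that("constant areas are flagged as no detectable build-up", {
  const <- BuildupSeries(seq(100, 1000, 100), rep(0.8, 10), rep(0.5, 10))
  fit <- fitBuildup(const, nDraws = 0)
  expect_false(fit$buildupDetected)
  # completed-before-first-observation series (too rapid to observe)
  rapid <- simulateBuildup(kObs = 10, times = seq(60, 1200, 60),
                           noiseSD = 0, seed = 1)
  fitR <- fitBuildup(rapid$series, nDraws = 0)
  expect_false(fitR$buildupDetected)
  expect_error(fitBuildup(BuildupSeries(1:4, 1:4, 1:4)), ">= 5")
})

test_that("noisy build-up ensembles are recovered without bias", {
  ks <- vapply(1:40, function(s) {
    sim <- simulateBuildup(kObs = 1e-3, noiseSD = 0.03, seed = 100 + s)
    fitBuildup(sim$series, nDraws = 0)$kObs
  }, numeric(1))
  expect_lt(abs(median(ks) / 1e-3 - 1), 0.10)
  # Monte Carlo error on k is reported and deterministic under a seed
  sim <- simulateBuildup(kObs = 1e-3, noiseSD = 0.03, seed = 5)
  f1 <- fitBuildup(sim$series, nDraws = 30, seed = 7)
  f2 <- fitBuildup(sim$series, nDraws = 30, seed = 7)
  expect_identical(f1$kObsSD, f2$kObsSD)
  expect_gt(f1$kObsSD, 0)
})
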