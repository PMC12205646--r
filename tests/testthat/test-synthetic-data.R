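# Generators: determinism, truth records, and zero-noise fidelity.

test_that("every generator is reproducible under a fixed seed", {
  p <- FastExchangeParams(25, 8 * 1500, 1500)
  expect_identical(simulateDispersion(p, seed = 9)$profile@r2Obs,
                   simulateDispersion(p, seed = 9)$profile@r2Obs)
  pk <- data.frame(center_ppm = -60, t2_ms = 50, area = 1)
  expect_identical(simulateSpectrum(pk, noiseSD = 0.1, seed = 9),
                   simulateSpectrum(pk, noiseSD = 0.1, seed = 9))
  expect_identical(simulatePlate(seed = 9)$plate$a340,
                   simulatePlate(seed = 9)$plate$a340)
  expect_identical(simulateTrajectory(seed = 9)$window@coords,
                   simulateTrajectory(seed = 9)$window@coords)
  expect_identical(simulateBuildup(noiseSD = 0.05, seed = 9)$series@areaNM,
                   simulateBuildup(noiseSD = 0.05, seed = 9)$series@areaNM)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateDispersion(p, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("truth records carry the seed and design parameters", {
  p <- FastExchangeParams(25, 8 * 1500, 1500)
  tr <- simulateDispersion(p, seed = 31)$truth
  expect_equal(tr$seed, 31)
  expect_equal(tr$kex, 1500)
  trP <- simulatePlate(seed = 4)$truth
  expect_equal(trP$seed, 4)
  expect_equal(trP$panel$L18D, 2.5)
  expect_equal(trP$delta_symm$L18D, 1.5)
})

test_that("zero-noise dispersion equals the model curve", {
  p <- FastExchangeParams(25, 8 * 1500, 1500)
  sim <- simulateDispersion(p, noiseSD = 0, seed = 1)
  expect_equal(sim$profile@r2Obs,
               r2FastExchange(p, sim$profile@nuCPMG), tolerance = 1e-14)
  expect_length(sim$profile@nuCPMG, 11)
})

test_that("noise averages out across a dispersion ensemble", {
  p <- FastExchangeParams(25, 8 * 1500, 1500)
  grid <- defaultCPMGGrid()
  clean <- r2FastExchange(p, grid)
  draws <- vapply(1:400, function(s)
    simulateDispersion(p, noiseSD = 0.5, seed = s)$profile@r2Obs,
    numeric(11))
  expect_lt(max(abs(rowMeans(draws) - clean)), 4 * 0.5 / sqrt(400))
})

test_that("zero-peak spectra are pure noise and peaks obey closed form", {
  noise <- simulateSpectrum(data.frame(center_ppm = numeric(),
                                       t2_ms = numeric(),
                                       area = numeric()),
                            noiseSD = 0.3, seed = 2)
  expect_lt(abs(mean(noise$spectrum@intensity)), 0.05)
  expect_equal(sd(noise$spectrum@intensity), 0.3, tolerance = 0.05)
})

test_that("a fully correlated region yields a block of ones", {
  sim <- suppressMessages(
    simulateTrajectory(regionSizes = c(a = 5), withinCorr = 1,
                       nFrames = 40, seed = 6))
  C <- dccmMatrix(computeDCCM(sim$window))
  expect_gt(min(C), 0.999)
})

test_that("non-positive-definite correlation requests are projected", {
  # three regions mutually at -0.9 cannot all anticorrelate: not PD
  expect_message(
    sim <- simulateTrajectory(regionSizes = c(a = 3, b = 3, c = 3),
                              withinCorr = 0.9, betweenCorr = -0.9,
                              nFrames = 30, seed = 8),
    "positive definite")
  expect_gt(sim$truth$pdProjectionDistance, 0)
  # the realized matrix is a valid correlation matrix
  expect_s4_class(computeDCCM(sim$window), "DCCMResult")
})

test_that("zero-noise plates recover the generator Delta values", {
  sim <- simulatePlate(noiseSD = 0, seed = 11)
  acts <- plateActivities(sim$plate, sim$wellmap)
  dm <- buildDeltaMatrix(acts)
  v <- deltaValues(dm)
  for (lab in names(sim$truth$panel))
    expect_equal(v[lab, lab], sim$truth$delta_symm[[lab]],
                 tolerance = 1e-9)
  for (key in names(sim$truth$heterodimers)) {
    pair <- strsplit(key, ":")[[1]]
    i <- max(match(pair, sampleLabels(dm)))
    j <- min(match(pair, sampleLabels(dm)))
    expect_equal(v[i, j], sim$truth$heterodimers[[key]]$delta_asymm,
                 tolerance = 1e-9)
  }
})
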