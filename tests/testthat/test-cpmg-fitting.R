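# Dispersion fitting, Monte Carlo errors, temperature series, and
# flat-vs-exchange model selection.

test_that("noise-free profiles are recovered to optimizer tolerance", {
  cases <- list(c(25, 8, 1500), c(12, 2, 400), c(40, 20, 8000))
  for (cs in cases) {
    truth <- FastExchangeParams(cs[1], cs[2] * cs[3], cs[3])
    prof <- simulateDispersion(truth, noiseSD = 0, seed = 1)$profile
    fit <- fitDispersion(prof)
    expect_true(fit@converged)
    expect_equal(r20(fit), cs[1], tolerance = 1e-6)
    expect_equal(rex(fit), cs[2] * cs[3], tolerance = 1e-6)
    expect_equal(kex(fit), cs[3], tolerance = 1e-6)
  }
})

test_that("a flat profile fits to negligible exchange amplitude", {
  prof <- DispersionProfile(defaultCPMGGrid(), rep(23.4, 11))
  fit <- fitDispersion(prof)
  expect_lt(rex(fit) / kex(fit), 1e-6)   # plateau ~ 0
  expect_equal(r20(fit), 23.4, tolerance = 1e-6)
})

test_that("the fit is invariant under data-point reordering", {
  truth <- FastExchangeParams(25, 8 * 1500, 1500)
  sim <- simulateDispersion(truth, noiseSD = 0.5, seed = 4)
  prof <- sim$profile
  perm <- c(6, 1, 11, 3, 9, 2, 8, 5, 10, 4, 7)
  prof2 <- DispersionProfile(nuCPMG(prof)[perm], r2Obs(prof)[perm],
                             prof@r2Err[perm])
  f1 <- fitDispersion(prof); f2 <- fitDispersion(prof2)
  expect_equal(kex(f1), kex(f2), tolerance = 1e-9)
  expect_equal(f1@sse, f2@sse, tolerance = 1e-9)
})

test_that("too few points raise an insufficient-data error", {
  prof <- DispersionProfile(c(50, 200, 800), c(25, 24, 23))
  expect_error(fitDispersion(prof), "insufficient data")
})

test_that("Monte Carlo errors are deterministic and scale with noise", {
  truth <- FastExchangeParams(25, 8 * 1500, 1500)
  sim <- simulateDispersion(truth, noiseSD = 0.5, seed = 2)
  fit <- fitDispersion(sim$profile)
  mc1 <- monteCarloErrors(sim$profile, fit, nDraws = 60, seed = 42)
  mc2 <- monteCarloErrors(sim$profile, fit, nDraws = 60, seed = 42)
  expect_identical(paramErrs(mc1), paramErrs(mc2))
  expect_identical(mcSamples(mc1), mcSamples(mc2))
  expect_equal(nrow(mcSamples(mc1)), 60)
  expect_error(monteCarloErrors(sim$profile, fit, nDraws = 1), "2 draws")

  # vanishing noise gives vanishing parameter errors
  sim0 <- simulateDispersion(truth, noiseSD = 1e-9, seed = 3)
  fit0 <- fitDispersion(sim0$profile)
  mc0 <- monteCarloErrors(sim0$profile, fit0, nDraws = 40, seed = 1)
  expect_lt(paramErrs(mc0)[["r2_0"]], 1e-6)
  expect_lt(paramErrs(mc0)[["kex"]] / kex(fit0), 1e-5)

  # errors shrink roughly in proportion to the noise SD
  simA <- simulateDispersion(truth, noiseSD = 0.2, seed = 5)
  simB <- simulateDispersion(truth, noiseSD = 0.8, seed = 5)
  eA <- paramErrs(monteCarloErrors(simA$profile, fitDispersion(simA$profile),
                                   nDraws = 120, seed = 9))
  eB <- paramErrs(monteCarloErrors(simB$profile, fitDispersion(simB$profile),
                                   nDraws = 120, seed = 9))
  expect_lt(eA[["r2_0"]], eB[["r2_0"]])
  ratio <- eB[["r2_0"]] / eA[["r2_0"]]
  expect_gt(ratio, 2); expect_lt(ratio, 8)   # nominal 4
})

test_that("temperature series fits independently and keeps order", {
  kexTruth <- c(800, 1500, 2600)
  profs <- lapply(seq_along(kexTruth), function(i)
    simulateDispersion(FastExchangeParams(25, 8 * kexTruth[i],
                                          kexTruth[i]),
                       noiseSD = 0, temperature = c(10, 25, 40)[i],
                       seed = i)$profile)
  fits <- fitTemperatureSeries(profs)
  got <- vapply(fits, kex, numeric(1))
  expect_equal(got, kexTruth, tolerance = 1e-5)
  expect_true(all(diff(got) > 0))
  # single profile reduces to fitDispersion
  one <- fitTemperatureSeries(profs[1])
  expect_equal(kex(one[[1]]), kex(fitDispersion(profs[[1]])))
  # empty input errors; a bad profile yields an error object in place
  expect_error(fitTemperatureSeries(list()), "empty")
  mixed <- fitTemperatureSeries(
    c(profs[1], list(DispersionProfile(c(50, 100, 200), c(25, 24, 23)))))
  expect_s4_class(mixed[[1]], "CPMGFit")
  expect_s3_class(mixed[[2]], "simpleError")
})

test_that("model selection prefers the correct model at the extremes", {
  flat <- DispersionProfile(defaultCPMGGrid(),
                            22 + c(0.1, -0.2, 0.15, 0, -0.1, 0.05,
                                   -0.05, 0.2, -0.15, 0.1, 0),
                            rep(0.15, 11))
  cmpF <- compareFlatVsExchange(flat, nullDraws = 500)
  expect_identical(cmpF$preferred, "flat")
  strong <- simulateDispersion(FastExchangeParams(25, 8 * 1500, 1500),
                               noiseSD = 0.5, seed = 8)$profile
  cmpS <- compareFlatVsExchange(strong, nullDraws = 500)
  expect_identical(cmpS$preferred, "exchange")
  expect_lt(cmpS$pValue, 0.01)
  expect_error(compareFlatVsExchange(
    DispersionProfile(c(50, 100, 300, 700), rep(20, 4))), ">= 5 points")
})
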