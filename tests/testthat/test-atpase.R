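# Coupled-assay rate extraction, background subtraction, mixture
# deconvolution, and the Delta modulation matrix.

test_that("a linear NADH decay yields the exact turnover rate", {
  times <- seq(0, 30, 2)
  rate <- 1.2                      # uM ATP / min
  conc <- 5                        # uM dimer
  a340 <- 3.7 - rate * 1e-6 * 6220 * times
  got <- rateFromCurve(times, a340, conc)
  expect_equal(as.numeric(got), rate / conc, tolerance = 1e-10)
  flat <- rateFromCurve(times, rep(3.7, length(times)), conc)
  expect_equal(as.numeric(flat), 0)
  expect_error(rateFromCurve(1:4, rep(1, 4), 5), ">= 5 points")
  expect_error(rateFromCurve(times, a340, 0), "> 0")
})

test_that("window selection drops late-curve curvature", {
  times <- seq(0, 60, 1)
  # linear until NADH runs out at 20 min, flat afterwards
  a340 <- pmax(3.7 - 0.05 * times, 3.7 - 0.05 * 20)
  got <- rateFromCurve(times, a340, 5)
  # the full-curve slope would be ~ -0.017; the selected window must
  # stay close to the true initial slope (R^2 gate admits a couple of
  # post-depletion points, so exact equality is not expected)
  expect_equal(attr(got, "slope"), -0.05, tolerance = 0.1)
  expect_lte(attr(got, "windowPoints"), 25)
})

test_that("an A340 rise beyond noise raises an assay anomaly warning", {
  times <- seq(0, 30, 2)
  set.seed(3)
  a340 <- 3.0 + 0.02 * times + rnorm(length(times), 0, 0.001)
  expect_warning(rateFromCurve(times, a340, 5), "anomaly")
})

test_that("background subtraction combines replicates in quadrature", {
  got <- subtractBackground(c(9, 10, 11), c(1.5, 2, 2.5))
  expect_equal(got$rate, 8)
  expect_equal(got$sd, sqrt(sd(c(9, 10, 11))^2 + sd(c(1.5, 2, 2.5))^2))
  expect_equal(got$nReps, 3)
  expect_equal(subtractBackground(5, 5)$rate, 0)
  expect_warning(clamped <- subtractBackground(c(1, 1.2), c(2, 2.2)),
                 "clamped")
  expect_equal(clamped$rate, 0)
  expect_error(subtractBackground(numeric(0), 1), "replicate")
})

test_that("mixing fractions give binomial dimer proportions", {
  expect_equal(unname(mixtureComposition(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(mixtureComposition(1)), c(1, 0, 0))
  expect_equal(unname(mixtureComposition(0.3)), c(0.09, 0.42, 0.49))
  expect_equal(sum(mixtureComposition(0.37)), 1)
  expect_error(mixtureComposition(1.2), "\\[0, 1\\]")
})

test_that("heterodimer deconvolution reproduces the worked example", {
  expect_equal(heterodimerActivity(1.6, 0, 2.5), 1.95)
  expect_equal(heterodimerActivity(1, 1, 1), 1)
  # exact inverse of the composition-weighted mixture mean
  set.seed(21)
  for (k in 1:200) {
    a <- runif(1, 0, 3); h <- runif(1, 0, 3); b <- runif(1, 0, 3)
    mix <- 0.25 * a + 0.5 * h + 0.25 * b
    expect_equal(heterodimerActivity(mix, a, b), h, tolerance = 1e-12)
  }
  expect_error(heterodimerActivity(Inf, 0, 1), "finite")
})

test_that("Delta statistics match their definitions", {
  expect_equal(deltaAsymm(1.95, 1.6), 0.35)
  expect_equal(deltaAsymm(1.2, 1.2), 0)
  expect_equal(deltaSymm(2.5), 1.5)
  expect_equal(deltaSymm(0), -1)
  expect_equal(deltaSymm(1), 0)
  # no asymmetric modulation when the mixture equals the homodimer mean
  set.seed(9)
  for (k in 1:50) {
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    mix <- 0.25 * a + 0.5 * ((a + b) / 2) + 0.25 * b
    expect_equal(deltaAsymm(heterodimerActivity(mix, a, b), mix), 0,
                 tolerance = 1e-12)
  }
})

test_that("fold stimulation handles dead basal samples", {
  expect_equal(foldStimulation(20, 1), 20)
  expect_equal(foldStimulation(3, 3), 1)
  expect_error(foldStimulation(5, 0), "undefined")
})

test_that("the Delta matrix matches a hand-worked two-variant case", {
  # homodimers: A = 1 (WT), B = 2.5; mixture measured at 1.6
  # hetD = (1.6 - 0.25*1 - 0.25*2.5)/0.5 = 1.45; Dasymm = -0.15
  rec <- data.frame(subunit1 = c("A", "B", "A"),
                    subunit2 = c("A", "B", "B"),
                    fractional_wt = c(1, 2.5, 1.6),
                    fractional_sd = c(0.1, 0.2, 0.1))
  dm <- buildDeltaMatrix(rec)
  v <- deltaValues(dm)
  expect_equal(v["A", "A"], 0)
  expect_equal(v["B", "B"], 1.5)
  expect_equal(v["B", "A"], 1.45 - 1.6)
  expect_true(is.na(v["A", "B"]))
  e <- deltaErrors(dm)
  expect_equal(e["B", "A"],
               sqrt(0.1^2 + 0.25 * 0.1^2 + 0.25 * 0.2^2))
  # WT alone gives a 1x1 zero diagonal
  solo <- buildDeltaMatrix(data.frame(subunit1 = "WT", subunit2 = "WT",
                                      fractional_wt = 1))
  expect_equal(deltaValues(solo)[1, 1], 0)
})

test_that("mixtures without homodimer references stay NA with a note", {
  rec <- data.frame(subunit1 = c("A", "A"), subunit2 = c("A", "C"),
                    fractional_wt = c(1, 0.8))
  dm <- buildDeltaMatrix(rec)
  expect_true(is.na(deltaValues(dm)["C", "A"]))
  expect_match(attr(dm, "issues"), "lacks a homodimer reference")
})

test_that("plate pipeline requires a WT reference for normalization", {
  sim <- simulatePlate(panel = c(WT = 1, L18D = 2.5), noiseSD = 0,
                       seed = 2)
  wm <- sim$wellmap
  wm$subunit1[wm$subunit1 == "WT"] <- "XX"
  wm$subunit2[wm$subunit2 == "WT"] <- "XX"
  expect_error(plateActivities(sim$plate, wm), "WT normalization failed")
})

test_that("replicate SDs on Delta shrink with replicate count", {
  sdOf <- function(nReps, seed) {
    sim <- simulatePlate(panel = c(WT = 1, L18D = 2.5),
                         noiseSD = 0.004, nReps = nReps, seed = seed)
    acts <- plateActivities(sim$plate, sim$wellmap)
    deltaErrors(buildDeltaMatrix(acts))["L18D", "L18D"]
  }
  s4 <- mean(vapply(1:6, function(s) sdOf(4, s), numeric(1)))
  s16 <- mean(vapply(1:6, function(s) sdOf(16, s), numeric(1)))
  expect_lt(s16, s4)
})
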