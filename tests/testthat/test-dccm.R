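# Superposition, cross-correlation matrices, and region totals.

rigidize <- function(coords, R, t) {
  out <- coords
  for (f in seq_len(dim(coords)[1]))
    out[f, , ] <- coords[f, , , drop = TRUE] %*% t(R) +
      matrix(t, dim(coords)[2], 3, byrow = TRUE)
  out
}

makeWindow <- function(coords, spacing = 10) {
  TrajectoryWindow(coords,
                   data.frame(resno = seq_len(dim(coords)[2]),
                              elety = "CA"),
                   frameSpacing = spacing)
}

test_that("rigidly moved frames superpose exactly onto the reference", {
  sim <- simulateTrajectory(regionSizes = c(a = 6), withinCorr = 0.3,
                            nFrames = 5, seed = 1)
  co <- sim$window@coords
  # copy frame 1 into all frames, each under a different rigid motion
  set.seed(2)
  for (f in 2:5) {
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    co[f, , ] <- co[1, , , drop = TRUE] %*% t(R) +
      matrix(runif(3, -20, 20), 6, 3, byrow = TRUE)
  }
  w <- makeWindow(co)
  sup <- suppressWarnings(superpose(w, atoms = "CA"))
  expect_lt(max(attr(sup, "rmsd")), 1e-8)
  # identity input is unchanged
  idw <- makeWindow(sim$window@coords)
  supId <- suppressWarnings(superpose(idw, atoms = "CA"))
  expect_lt(max(abs(supId@coords[1, , ] - idw@coords[1, , ])), 1e-10)
})

test_that("superposition never increases the fit-selection RMSD", {
  sim <- simulateTrajectory(nFrames = 20, rigidMotion = TRUE, seed = 5)
  w <- sim$window
  ref <- w@coords[1, , , drop = TRUE]
  before <- vapply(seq_len(20), function(f)
    sqrt(mean(rowSums((w@coords[f, , , drop = TRUE] - ref)^2))),
    numeric(1))
  sup <- superpose(w, atoms = "CA")
  expect_true(all(attr(sup, "rmsd") <= before + 1e-10))
  expect_error(superpose(makeWindow(sim$window@coords[, 1:2, ,
                                                      drop = FALSE])),
               "underdetermined")
})

test_that("superposed RMSD agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  sim <- simulateTrajectory(regionSizes = c(a = 8, b = 8),
                            withinCorr = 0.5, betweenCorr = -0.3,
                            nFrames = 12, rigidMotion = TRUE, seed = 7)
  w <- sim$window
  sup <- superpose(w, atoms = "CA")
  nf <- dim(w@coords)[1]
  flat <- t(vapply(seq_len(nf), function(f)
    as.numeric(t(w@coords[f, , , drop = TRUE])), numeric(3 * 16)))
  fitted <- bio3d::fit.xyz(flat[1, ], flat, fixed.inds = 1:(3 * 16),
                           mobile.inds = 1:(3 * 16))
  rmsdOracle <- vapply(seq_len(nf), function(f)
    sqrt(mean(rowSums((matrix(fitted[f, ], ncol = 3, byrow = TRUE) -
                         matrix(flat[1, ], ncol = 3,
                                byrow = TRUE))^2))), numeric(1))
  expect_equal(attr(sup, "rmsd"), rmsdOracle, tolerance = 1e-8)
})

test_that("the DCCM equals a brute-force double-loop computation", {
  sim <- simulateTrajectory(regionSizes = c(a = 4, b = 5),
                            withinCorr = 0.5, betweenCorr = -0.4,
                            nFrames = 15, seed = 3)
  got <- dccmMatrix(computeDCCM(sim$window))
  ref <- bruteDCCM(sim$window@coords)
  expect_lt(max(abs(got - unname(ref))), 1e-12)
  expect_equal(unname(diag(got)), rep(1, 9))
  expect_lt(max(abs(got - t(got))), 1e-14)
})

test_that("DCCM agrees with the bio3d implementation", {
  skip_if_not_installed("bio3d")
  sim <- simulateTrajectory(regionSizes = c(a = 5, b = 5),
                            withinCorr = 0.6, betweenCorr = -0.2,
                            nFrames = 25, seed = 13)
  got <- dccmMatrix(computeDCCM(sim$window))
  nf <- 25
  flat <- t(vapply(seq_len(nf), function(f)
    as.numeric(t(sim$window@coords[f, , , drop = TRUE])),
    numeric(3 * 10)))
  ref <- unclass(bio3d::dccm.xyz(flat))
  expect_lt(max(abs(got - unname(ref))), 1e-8)
})

test_that("perfectly shared and opposed motions give +1 and -1", {
  nf <- 12
  z <- rnorm(nf)
  co <- array(0, c(nf, 2, 3))
  co[, 1, 1] <- z; co[, 2, 1] <- z + 5
  shared <- suppressWarnings(computeDCCM(makeWindow(co)))
  expect_equal(unname(dccmMatrix(shared)[1, 2]), 1)
  co[, 2, 1] <- -z
  opposed <- suppressWarnings(computeDCCM(makeWindow(co)))
  expect_equal(unname(dccmMatrix(opposed)[1, 2]), -1)
  # a frozen atom is reported by residue number
  co[, 2, ] <- 3
  expect_error(suppressWarnings(computeDCCM(makeWindow(co))),
               "zero-variance.*2")
})

test_that("total correlation counts each unordered pair once", {
  ones <- matrix(1, 7, 7)
  d <- new("DCCMResult", matrix = ones, residues = 1:7,
           regionTotals = setNames(numeric(0), character(0)))
  expect_equal(totalCorrelation(d, 1:3, 4:7), 12)
  expect_equal(totalCorrelation(d, 4:7, 4:7), 6)
  idm <- new("DCCMResult", matrix = diag(7), residues = 1:7,
             regionTotals = setNames(numeric(0), character(0)))
  expect_equal(totalCorrelation(idm, 1:3, 4:7), 0)
  expect_error(totalCorrelation(d, 90:95, 1:3), "no residues")
})

test_that("total correlation is symmetric, additive, and brute-forced", {
  sim <- simulateTrajectory(regionSizes = c(a = 4, b = 3, c = 3),
                            withinCorr = 0.5, betweenCorr = 0.1,
                            nFrames = 30, seed = 17)
  d <- computeDCCM(sim$window)
  m <- dccmMatrix(d)
  A <- 1:4; B <- 5:7; C <- 8:10
  expect_equal(totalCorrelation(d, A, B), totalCorrelation(d, B, A))
  for (ra in list(A, B, 2:6, 1:10)) for (rb in list(C, 3:9, 1:10))
    expect_equal(totalCorrelation(d, ra, rb),
                 bruteTotalCorrelation(m, d@residues, ra, rb),
                 tolerance = 1e-12)
  # union additivity over disjoint sub-regions
  expect_equal(totalCorrelation(d, union(A, B), union(A, B)),
               totalCorrelation(d, A, A) + totalCorrelation(d, B, B) +
                 totalCorrelation(d, A, B),
               tolerance = 1e-12)
})

test_that("windowed analysis reduces to a single full-window DCCM", {
  sim <- simulateTrajectory(nFrames = 30, frameSpacing = 10, seed = 19)
  w <- sim$window
  series <- windowedDCCM(w, stepNs = 10, windowNs = 290,
                         fitAtoms = "CA")
  expect_length(series, 1)
  direct <- computeDCCM(superpose(w, atoms = "CA"))
  expect_lt(max(abs(dccmMatrix(series[[1]]) - dccmMatrix(direct))),
            1e-12)
  expect_error(windowedDCCM(w, stepNs = 400, windowNs = 290),
               "exceed")
  expect_error(windowedDCCM(w, stepNs = 10, windowNs = 9000),
               "shorter")
  # constant trajectory has no displacement variance
  const <- array(rep(w@coords[1, , ], each = 4), c(4, dim(w@coords)[2], 3))
  expect_error(suppressWarnings(
    windowedDCCM(makeWindow(const), stepNs = 10, windowNs = 30,
                 fitAtoms = "CA")), "zero-variance")
  # tiled placement covers the trajectory with >= 2 windows
  tiled <- windowedDCCM(w, stepNs = 10, windowNs = 130, fitAtoms = "CA",
                        tile = TRUE)
  expect_gte(length(tiled), 2)
})

test_that("DCCM is invariant under injected rigid-body motion", {
  still <- simulateTrajectory(nFrames = 40, rigidMotion = FALSE, seed = 23)
  moving <- simulateTrajectory(nFrames = 40, rigidMotion = TRUE, seed = 23)
  dStill <- computeDCCM(superpose(still$window, atoms = "CA"))
  dMoving <- computeDCCM(superpose(moving$window, atoms = "CA"))
  expect_lt(max(abs(dccmMatrix(dStill) - dccmMatrix(dMoving))), 1e-10)
})
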