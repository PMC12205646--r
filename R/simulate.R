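# Synthetic-data generators: every input class the analysis modules
# consume, with recorded seeds and machine-readable ground truth.
# Noise is Gaussian throughout, matching the least-squares assumptions
# of the fitters.

.withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))
  force(expr)
}

#' Default 11-point CPMG grid
#'
#' Eleven CPMG field strengths evenly spaced over 50-1000 Hz, the
#' typical per-profile design (11 relaxation delays).
#' @return numeric vector of nu_CPMG values, Hz
#' @export
defaultCPMGGrid <- function() seq(50, 1000, length.out = 11)

#' Simulate a CPMG dispersion profile
#'
#' Evaluates the fast-exchange model on the grid and adds iid Gaussian
#' noise of standard deviation `noiseSD` (also recorded as the per-point
#' error of the profile when positive).
#'
#' @param params true [FastExchangeParams-class]
#' @param grid CPMG field strengths, Hz
#' @param noiseSD R2 noise, 1/s
#' @param temperature,fieldMHz,label profile metadata
#' @param seed integer seed
#' @return list with `profile` ([DispersionProfile-class]) and `truth`
#'   (list of generator parameters, noise and seed)
#' @export
simulateDispersion <- function(params, grid = defaultCPMGGrid(),
                               noiseSD = 0.5, temperature = 25,
                               fieldMHz = 657, label = "synthetic",
                               seed = 1) {
  stopifnot(is(params, "FastExchangeParams"))
  validObject(params)
  clean <- r2FastExchange(params, grid)
  r2 <- .withSeed(seed, clean + rnorm(length(grid), 0, noiseSD))
  prof <- DispersionProfile(
    nuCPMG = grid, r2Obs = r2,
    r2Err = if (noiseSD > 0) rep(noiseSD, length(grid)) else numeric(0),
    temperature = temperature, fieldMHz = fieldMHz, label = label)
  list(profile = prof,
       truth = list(r2_0 = params@r2_0, rex = params@rex, kex = params@kex,
                    noiseSD = noiseSD, seed = seed, grid = grid))
}

#' Simulate a 1-D spectrum as a sum of Lorentzians
#'
#' Each peak is a Lorentzian of analytic area `area` whose FWHM follows
#' from its transverse relaxation time, \eqn{FWHM_{Hz} = 1/(\pi T_2)};
#' a noise-free peak has height \eqn{2\,area/(\pi\,FWHM)} at its center.
#'
#' @param peaks data.frame with columns `center_ppm`, `t2_ms`, `area`
#'   (zero rows give pure noise)
#' @param ppmRange axis limits, ppm
#' @param points number of axis points
#' @param noiseSD Gaussian intensity noise
#' @param fieldMHz,temperature spectrum metadata
#' @param seed integer seed
#' @return list with `spectrum` ([Spectrum1D-class]) and `truth`
#' @export
simulateSpectrum <- function(peaks, ppmRange = c(-63, -58), points = 4096,
                             noiseSD = 0, fieldMHz = 657, temperature = 25,
                             seed = 1) {
  ppm <- seq(ppmRange[1], ppmRange[2], length.out = points)
  intensity <- rep(0, points)
  if (nrow(peaks)) {
    stopifnot(all(c("center_ppm", "t2_ms", "area") %in% names(peaks)))
    for (k in seq_len(nrow(peaks))) {
      fwhmHz <- 1000 / (pi * peaks$t2_ms[k])
      intensity <- intensity +
        .lorentz(ppm, peaks$center_ppm[k], fwhmHz / fieldMHz,
                 peaks$area[k])
    }
  }
  if (noiseSD > 0)
    intensity <- .withSeed(seed, intensity + rnorm(points, 0, noiseSD))
  list(spectrum = Spectrum1D(ppm, intensity, fieldMHz, temperature),
       truth = list(peaks = peaks, noiseSD = noiseSD, seed = seed))
}

#' Default homodimer activity panel
#'
#' Fractional WT activities of the assayed subunit variants: WT defines
#' 1, the helix-1 L18D variant is 2.5-fold stimulated, the strap
#' variants F6D/F8D and F6D/F8D/L18D and the catalytic-glutamate variant
#' E33A lack activity.
#' @return named numeric of per-homodimer fractional WT activities
#' @export
defaultActivityPanel <- function() {
  c(WT = 1, L18D = 2.5, F6DF8D = 0, F6DF8DL18D = 0, E33A = 0)
}

#' Default heterodimer activity overrides
#'
#' Pure-heterodimer fractional activities that differ from the average
#' of their homodimers: a catalytically dead F6D/F8D subunit
#' asymmetrically stimulates a WT partner (hetD 1.9, i.e. a 1.2x mixture
#' and Delta_asymm +0.7) and an L18D partner (hetD 1.95, a 1.6x mixture
#' and Delta_asymm +0.35).  Unlisted pairs default to the homodimer
#' average (no asymmetric modulation).
#' @return named numeric, names "A:B"
#' @export
defaultHeterodimerActivities <- function() {
  c("WT:F6DF8D" = 1.9, "F6DF8D:L18D" = 1.95)
}

.hetLookup <- function(hetActivities, a, b, fallback) {
  v <- hetActivities[paste(a, b, sep = ":")]
  if (is.na(v)) v <- hetActivities[paste(b, a, sep = ":")]
  if (is.na(v)) fallback else unname(v)
}

#' Simulate an NADH-coupled ATPase assay plate
#'
#' Generates linear NADH-depletion progress curves for homodimer wells,
#' 1:2:1 mixture wells (binomial composition from 1:1 subunit mixing),
#' matched NVP-AUY922-inhibited background wells, and optional +Aha1
#' wells, with Gaussian A340 noise.  Activities are specified on the
#' fraction-of-WT scale and converted to absolute turnover through
#' `wtRate`; mixture wells combine the (0.25, 0.5, 0.25) dimer species,
#' with heterodimer activities taken from `hetActivities` (falling back
#' to the homodimer average).
#'
#' @param panel named numeric of homodimer fractional WT activities
#' @param hetActivities named numeric "A:B" heterodimer overrides
#' @param pairs 2-column character matrix of subunit pairs to mix;
#'   default all unordered pairs of the panel
#' @param aha1Folds named numeric: for each listed homodimer, the Aha1
#'   fold stimulation applied to its basal rate (a dead homodimer stays
#'   dead, leaving the fold undefined downstream)
#' @param wtRate absolute WT turnover, uM ATP / min / uM dimer
#' @param backgroundRate Hsp90-independent NADH depletion, uM / min
#' @param hsp90Um dimer concentration in homodimer and mixture wells, uM
#' @param nadh0Um initial NADH concentration, uM (sets the A340 start)
#' @param times sampling times, min
#' @param epsilonNADH extinction coefficient, 1/(M cm)
#' @param noiseSD A340 noise
#' @param nReps replicates per condition (four in the assay design)
#' @param seed integer seed
#' @return list with `plate` (long data.frame), `wellmap` (data.frame)
#'   and `truth` (per-sample expected fractional activities and the
#'   expected Delta values)
#' @export
simulatePlate <- function(panel = defaultActivityPanel(),
                          hetActivities = defaultHeterodimerActivities(),
                          pairs = NULL, aha1Folds = NULL,
                          wtRate = 0.5, backgroundRate = 0.3,
                          hsp90Um = 5, nadh0Um = 600,
                          times = seq(0, 30, by = 2),
                          epsilonNADH = 6220, noiseSD = 0.002,
                          nReps = 4, seed = 1) {
  labs <- names(panel)
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
    pairs <- cbind(labs[idx[, "row"]], labs[idx[, "col"]])
  }
  conditions <- data.frame(sample_label = paste0(labs, ":", labs),
                           subunit1 = labs, subunit2 = labs,
                           aha1 = 0,
                           frac = unname(panel),
                           hsp90_um = hsp90Um, stringsAsFactors = FALSE)
  truthHet <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    het <- .hetLookup(hetActivities, a, b, (panel[[a]] + panel[[b]]) / 2)
    mixFrac <- 0.25 * panel[[a]] + 0.5 * het + 0.25 * panel[[b]]
    truthHet[[paste(a, b, sep = ":")]] <-
      list(het = het, homhetmix = mixFrac,
           delta_asymm = het - mixFrac)
    conditions <- rbind(conditions, data.frame(
      sample_label = paste0(a, ":", b), subunit1 = a, subunit2 = b,
      aha1 = 0, frac = mixFrac, hsp90_um = hsp90Um,
      stringsAsFactors = FALSE))
  }
  if (!is.null(aha1Folds)) {
    for (lab in names(aha1Folds)) {
      conditions <- rbind(conditions, data.frame(
        sample_label = paste0(lab, ":", lab, "+Aha1"),
        subunit1 = lab, subunit2 = lab, aha1 = 1,
        frac = panel[[lab]] * aha1Folds[[lab]],
        hsp90_um = hsp90Um, stringsAsFactors = FALSE))
    }
  }
  a0 <- nadh0Um * 1e-6 * epsilonNADH
  .withSeed(seed, {
    wellRows <- list(); mapRows <- list(); wid <- 0L
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      rateUm <- cond$frac * wtRate * cond$hsp90_um   # uM ATP / min
      for (inhibited in c(0, 1)) {
        eff <- if (inhibited) backgroundRate else rateUm + backgroundRate
        for (rep_ in seq_len(nReps)) {
          wid <- wid + 1L
          wellId <- sprintf("W%03d", wid)
          a340 <- a0 - eff * 1e-6 * epsilonNADH * times +
            rnorm(length(times), 0, noiseSD)
          wellRows[[wid]] <- data.frame(well_id = wellId,
                                        time_min = times, a340 = a340,
                                        stringsAsFactors = FALSE)
          mapRows[[wid]] <- data.frame(
            well_id = wellId, sample_label = cond$sample_label,
            subunit1 = cond$subunit1, subunit2 = cond$subunit2,
            inhibited = inhibited, aha1 = cond$aha1,
            hsp90_um = cond$hsp90_um, replicate = rep_,
            stringsAsFactors = FALSE)
        }
      }
    }
    plate <- do.call(rbind, wellRows)
    wellmap <- do.call(rbind, mapRows)
    rownames(plate) <- rownames(wellmap) <- NULL
    list(plate = plate, wellmap = wellmap,
         truth = list(panel = as.list(panel),
                      heterodimers = truthHet,
                      delta_symm = as.list(panel - 1),
                      aha1Folds = as.list(aha1Folds),
                      wtRate = wtRate, backgroundRate = backgroundRate,
                      noiseSD = noiseSD, nReps = nReps, seed = seed))
  })
}

.nearestPD <- function(C, eps = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(C = C, dist = 0))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(outer(diag(M), diag(M)))
  list(C = M / d, dist = sqrt(sum((M / d - C)^2)))
}

.randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Simulate a trajectory window with prescribed block correlations
#'
#' Draws per-frame atomic displacements from a multivariate Gaussian
#' whose correlation matrix has a block structure: `withinCorr` inside
#' each region and `betweenCorr` between regions (a scalar, or a
#' regions x regions matrix for pair-specific levels).  The same
#' correlation structure is applied independently to x, y and z, on top
#' of mean CA positions laid out on a coarse helix (so the configuration
#' is never collinear and superposition is well conditioned).  A
#' requested correlation matrix that is not positive definite is
#' projected to the nearest positive-definite one, with the projection
#' distance recorded in the truth.  With `rigidMotion = TRUE` each frame
#' additionally receives a random rotation and translation, which
#' [superpose()] removes exactly.
#'
#' @param regionSizes named integer vector: atoms (one CA residue each)
#'   per region; residues are numbered consecutively from 1
#' @param withinCorr correlation between atoms of the same region
#' @param betweenCorr correlation between atoms of different regions
#' @param nFrames number of frames (80 frames at 10 ns spacing matches
#'   the 800 ns analysis window)
#' @param displacementSD per-axis displacement SD, Angstrom
#' @param rigidMotion add random per-frame rigid-body motion
#' @param frameSpacing ns between frames
#' @param seed integer seed
#' @return list with `window` ([TrajectoryWindow-class]), `regions`
#'   (named list of [Region()]) and `truth` (requested and realized
#'   correlation levels, PD projection distance, seed)
#' @export
simulateTrajectory <- function(regionSizes = c(helix1 = 14, gate = 32),
                               withinCorr = 0.6, betweenCorr = -0.5,
                               nFrames = 80, displacementSD = 1,
                               rigidMotion = FALSE, frameSpacing = 10,
                               seed = 1) {
  nr <- length(regionSizes)
  if (is.null(names(regionSizes)))
    names(regionSizes) <- paste0("region", seq_len(nr))
  N <- sum(regionSizes)
  block <- rep(seq_len(nr), regionSizes)
  B <- if (is.matrix(betweenCorr)) betweenCorr else
    matrix(betweenCorr, nr, nr)
  C <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    C[i, j] <- if (i == j) 1 else if (block[i] == block[j]) withinCorr
    else B[block[i], block[j]]
  }
  pd <- .nearestPD(C)
  if (pd$dist > 0)
    message("requested correlation matrix projected to nearest ",
            "positive definite (Frobenius distance ",
            format(pd$dist, digits = 3), ")")
  L <- t(chol(pd$C))
  # mean positions on a coarse helix, ~3.8 A between consecutive CAs
  tpar <- seq_len(N)
  base <- cbind(8 * cos(tpar * 0.6), 8 * sin(tpar * 0.6), 2.5 * tpar)
  coords <- array(NA_real_, c(nFrames, N, 3))
  .withSeed(seed, {
    # displacements first so the displacement stream is identical
    # whether or not rigid motion is added on top
    for (f in seq_len(nFrames)) {
      disp <- displacementSD * (L %*% matrix(rnorm(3 * N), N, 3))
      coords[f, , ] <- base + disp
    }
    if (rigidMotion) {
      for (f in seq_len(nFrames)) {
        R <- .randomRotation()
        coords[f, , ] <- coords[f, , ] %*% t(R) +
          matrix(rnorm(3, 0, 10), N, 3, byrow = TRUE)
      }
    }
  })
  edges <- cumsum(regionSizes)
  firsts <- c(1, head(edges, -1) + 1)
  regions <- mapply(function(nm, a, b) Region(nm, a, b),
                    names(regionSizes), firsts, edges, SIMPLIFY = FALSE)
  window <- TrajectoryWindow(
    coords,
    data.frame(resno = seq_len(N), elety = "CA",
               stringsAsFactors = FALSE),
    frameSpacing = frameSpacing)
  list(window = window, regions = regions,
       truth = list(regionSizes = as.list(regionSizes),
                    withinCorr = withinCorr, betweenCorr = betweenCorr,
                    pdProjectionDistance = pd$dist,
                    nFrames = nFrames, displacementSD = displacementSD,
                    rigidMotion = rigidMotion, seed = seed))
}

#' Simulate a build-up time course
#'
#' Single-exponential two-state build-up with shared rate: the
#' clamp-closed area rises as \eqn{A_\infty(1 - e^{-k t})} while the NM
#' area decays toward its end level, plus Gaussian noise.
#'
#' @param kObs observed build-up rate, 1/s
#' @param aClosedInf clamp-closed plateau area
#' @param aNMStart,aNMEnd NM area at t = 0 and at completion
#' @param times sampling times, s
#' @param noiseSD Gaussian area noise
#' @param seed integer seed
#' @return list with `series` ([BuildupSeries-class]) and `truth`
#' @export
simulateBuildup <- function(kObs = 1e-3, aClosedInf = 1, aNMStart = 1,
                            aNMEnd = 0.2,
                            times = seq(0, 4000, length.out = 21),
                            noiseSD = 0, seed = 1) {
  e <- exp(-kObs * times)
  closed <- aClosedInf * (1 - e)
  nm <- aNMEnd + (aNMStart - aNMEnd) * e
  if (noiseSD > 0) {
    noisy <- .withSeed(seed, list(
      closed = pmax(closed + rnorm(length(times), 0, noiseSD), 0),
      nm = pmax(nm + rnorm(length(times), 0, noiseSD), 0)))
    closed <- noisy$closed; nm <- noisy$nm
  }
  list(series = BuildupSeries(times, nm, closed),
       truth = list(kObs = kObs, aClosedInf = aClosedInf,
                    aNMStart = aNMStart, aNMEnd = aNMEnd,
                    noiseSD = noiseSD, seed = seed))
}
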