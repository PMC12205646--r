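#' @import methods
#' @importFrom stats coef lm median pf rnorm sd setNames
#' @importFrom utils head
NULL

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Two-state fast-exchange parameters
#'
#' Holds the three parameters of the fast-exchange (Luz--Meiboom-type)
#' relaxation dispersion model: the intrinsic transverse relaxation rate
#' \eqn{R_{2,0}} (population-weighted average over the two states), the
#' exchange amplitude \eqn{R_{ex} = p_A p_B \Delta\omega^2}, and the
#' exchange rate constant \eqn{k_{ex}}.
#'
#' @slot r2_0 intrinsic transverse relaxation rate, 1/s
#' @slot rex exchange amplitude, rad^2/s^2 (see [rexPlateau()] for the
#'   alternative plateau convention in 1/s)
#' @slot kex exchange rate constant, 1/s
#' @export
setClass("FastExchangeParams",
  representation(r2_0 = "numeric", rex = "numeric", kex = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarNum(object@r2_0) || object@r2_0 < 0)
      msg <- c(msg, "'r2_0' must be a finite scalar >= 0")
    if (!.scalarNum(object@rex) || object@rex < 0)
      msg <- c(msg, "'rex' must be a finite scalar >= 0")
    if (!.scalarNum(object@kex) || object@kex <= 0)
      msg <- c(msg, "'kex' must be a finite scalar > 0")
    if (length(msg)) msg else TRUE
  })

#' @param r2_0,rex,kex model parameters (see slots)
#' @rdname FastExchangeParams-class
#' @export
FastExchangeParams <- function(r2_0, rex, kex) {
  new("FastExchangeParams", r2_0 = as.numeric(r2_0), rex = as.numeric(rex),
      kex = as.numeric(kex))
}

#' Two-state populations and chemical-shift separation
#'
#' Ground/excited-state populations and the chemical-shift difference
#' between the two exchanging states, the quantities that define the
#' exchange amplitude \eqn{R_{ex} = p_A p_B \Delta\omega^2}.
#'
#' @slot pA ground-state population, fraction in [0, 1]
#' @slot pB excited-state population, fraction; pA + pB = 1
#' @slot deltaOmega chemical-shift difference between the states, rad/s
#' @export
setClass("TwoStatePopulations",
  representation(pA = "numeric", pB = "numeric", deltaOmega = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarNum(object@pA) || object@pA < 0 || object@pA > 1)
      msg <- c(msg, "'pA' must lie in [0, 1]")
    if (!.scalarNum(object@pB) || object@pB < 0 || object@pB > 1)
      msg <- c(msg, "'pB' must lie in [0, 1]")
    if (.scalarNum(object@pA) && .scalarNum(object@pB) &&
        abs(object@pA + object@pB - 1) > 1e-8)
      msg <- c(msg, "'pA' + 'pB' must equal 1")
    if (!.scalarNum(object@deltaOmega))
      msg <- c(msg, "'deltaOmega' must be a finite scalar")
    if (length(msg)) msg else TRUE
  })

#' @param pA,pB state populations; if `pB` is missing it defaults to 1 - pA
#' @param deltaOmega chemical-shift difference, rad/s
#' @rdname TwoStatePopulations-class
#' @export
TwoStatePopulations <- function(pA, pB = 1 - pA, deltaOmega) {
  new("TwoStatePopulations", pA = as.numeric(pA), pB = as.numeric(pB),
      deltaOmega = as.numeric(deltaOmega))
}

#' A single-temperature CPMG relaxation dispersion profile
#'
#' One dispersion curve: effective transverse relaxation rates measured
#' over a grid of CPMG field strengths \eqn{\nu_{CPMG} = 1/(4\tau_{CPMG})}.
#'
#' @slot nuCPMG CPMG field strengths, Hz; strictly increasing
#' @slot r2Obs observed effective R2 per grid point, 1/s
#' @slot r2Err per-point standard error, 1/s; `numeric(0)` when unknown
#' @slot temperature sample temperature, degrees C
#' @slot fieldMHz 19F Larmor frequency, MHz
#' @slot label sample / state identifier
#' @export
setClass("DispersionProfile",
  representation(nuCPMG = "numeric", r2Obs = "numeric", r2Err = "numeric",
                 temperature = "numeric", fieldMHz = "numeric",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@nuCPMG)
    if (n == 0L) msg <- c(msg, "empty nuCPMG grid")
    if (length(object@r2Obs) != n)
      msg <- c(msg, "'r2Obs' and 'nuCPMG' must have equal length")
    if (any(!is.finite(object@nuCPMG)) || any(object@nuCPMG <= 0))
      msg <- c(msg, "all nuCPMG values must be finite and > 0")
    if (n > 1 && any(diff(object@nuCPMG) <= 0))
      msg <- c(msg, "'nuCPMG' must be strictly increasing")
    if (length(object@r2Err) && length(object@r2Err) != n)
      msg <- c(msg, "'r2Err' must be empty or match 'nuCPMG' in length")
    if (length(object@r2Err) && any(object@r2Err <= 0))
      msg <- c(msg, "'r2Err' values must be strictly positive")
    if (length(msg)) msg else TRUE
  })

#' @param nuCPMG,r2Obs,r2Err,temperature,fieldMHz,label see slots
#' @rdname DispersionProfile-class
#' @export
DispersionProfile <- function(nuCPMG, r2Obs, r2Err = numeric(0),
                              temperature = NA_real_, fieldMHz = 657,
                              label = "") {
  ord <- order(nuCPMG)
  r2Err <- if (length(r2Err)) as.numeric(r2Err)[ord] else numeric(0)
  new("DispersionProfile", nuCPMG = as.numeric(nuCPMG)[ord],
      r2Obs = as.numeric(r2Obs)[ord], r2Err = r2Err,
      temperature = as.numeric(temperature), fieldMHz = as.numeric(fieldMHz),
      label = as.character(label))
}

#' Result of fitting a dispersion profile
#'
#' @slot params fitted [FastExchangeParams-class]
#' @slot paramErrs one standard deviation per parameter (named r2_0, rex,
#'   kex); `NA` until [monteCarloErrors()] fills them
#' @slot sse weighted sum of squared residuals at the optimum
#' @slot nPoints number of data points fitted
#' @slot converged optimizer convergence flag
#' @slot mcSamples retained Monte Carlo parameter draws (draws x 3 matrix;
#'   zero rows when Monte Carlo was skipped)
#' @slot seed seed used for Monte Carlo draws (NA when skipped)
#' @export
setClass("CPMGFit",
  representation(params = "FastExchangeParams", paramErrs = "numeric",
                 sse = "numeric", nPoints = "integer", converged = "logical",
                 mcSamples = "matrix", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@sse < 0) msg <- c(msg, "'sse' must be >= 0")
    if (any(!is.na(object@paramErrs) & object@paramErrs < 0))
      msg <- c(msg, "'paramErrs' must be >= 0")
    if (!identical(sort(names(object@paramErrs)), c("kex", "r2_0", "rex")))
      msg <- c(msg, "'paramErrs' must be named r2_0, rex, kex")
    if (length(msg)) msg else TRUE
  })

#' A 1-D NMR spectrum
#'
#' @slot ppm chemical-shift axis, ppm; stored in increasing order
#' @slot intensity intensities, arbitrary units
#' @slot fieldMHz Larmor frequency, MHz (converts ppm widths to Hz)
#' @slot temperature degrees C
#' @export
setClass("Spectrum1D",
  representation(ppm = "numeric", intensity = "numeric",
                 fieldMHz = "numeric", temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@ppm) != length(object@intensity))
      msg <- c(msg, "'ppm' and 'intensity' must have equal length")
    if (length(object@ppm) > 1 && any(diff(object@ppm) <= 0))
      msg <- c(msg, "'ppm' must be strictly monotonic")
    if (length(msg)) msg else TRUE
  })

#' @param ppm,intensity,fieldMHz,temperature see slots; a decreasing ppm
#'   axis (the conventional left-to-right display order) is reversed
#'   internally
#' @rdname Spectrum1D-class
#' @export
Spectrum1D <- function(ppm, intensity, fieldMHz = 657,
                       temperature = NA_real_) {
  if (length(ppm) > 1 && ppm[1] > ppm[length(ppm)]) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  new("Spectrum1D", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      fieldMHz = as.numeric(fieldMHz), temperature = as.numeric(temperature))
}

#' Time course of peak areas after nucleotide addition
#'
#' Peak areas of the NM-associated and clamp-closed states as a function
#' of time since nucleotide (AMP-PNP) addition.
#'
#' @slot time seconds since nucleotide addition; non-negative, increasing
#' @slot areaNM peak area of the NM-associated state
#' @slot areaClosed peak area of the clamp-closed state
#' @export
setClass("BuildupSeries",
  representation(time = "numeric", areaNM = "numeric", areaClosed = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (length(object@areaNM) != n || length(object@areaClosed) != n)
      msg <- c(msg, "all fields must have equal length")
    if (any(object@time < 0)) msg <- c(msg, "'time' must be non-negative")
    if (n > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "'time' must be strictly increasing")
    if (any(object@areaNM < 0) || any(object@areaClosed < 0))
      msg <- c(msg, "areas must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param time,areaNM,areaClosed see slots
#' @rdname BuildupSeries-class
#' @export
BuildupSeries <- function(time, areaNM, areaClosed) {
  new("BuildupSeries", time = as.numeric(time), areaNM = as.numeric(areaNM),
      areaClosed = as.numeric(areaClosed))
}

#' A window of trajectory frames
#'
#' Cartesian coordinates for a set of atoms over trajectory frames,
#' together with the atom index (residue number + atom name) needed for
#' residue-range selections.
#'
#' @slot coords frames x atoms x 3 array, Angstrom
#' @slot atomIndex data.frame with columns `resno` (residue number) and
#'   `elety` (atom name, e.g. "CA"), one row per atom
#' @slot frameSpacing time between stored frames, ns
#' @export
setClass("TrajectoryWindow",
  representation(coords = "array", atomIndex = "data.frame",
                 frameSpacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "'coords' must be a frames x atoms x 3 array")
    else {
      if (d[1] < 2L) msg <- c(msg, "at least 2 frames required")
      if (nrow(object@atomIndex) != d[2])
        msg <- c(msg, "'atomIndex' rows must match the atom dimension")
    }
    if (!all(c("resno", "elety") %in% names(object@atomIndex)))
      msg <- c(msg, "'atomIndex' needs columns 'resno' and 'elety'")
    if (length(msg)) msg else TRUE
  })

#' @param coords,atomIndex,frameSpacing see slots
#' @rdname TrajectoryWindow-class
#' @export
TrajectoryWindow <- function(coords, atomIndex, frameSpacing = 10) {
  new("TrajectoryWindow", coords = coords,
      atomIndex = as.data.frame(atomIndex),
      frameSpacing = as.numeric(frameSpacing))
}

#' Dynamical cross-correlation matrix result
#'
#' @slot matrix residue x residue normalized displacement correlations,
#'   symmetric with unit diagonal, entries in [-1, 1]
#' @slot residues ordered residue numbers labelling rows/columns
#' @slot regionTotals named numeric of region-pair total correlations
#'   (off-diagonal sums counting each unordered pair once)
#' @export
setClass("DCCMResult",
  representation(matrix = "matrix", residues = "integer",
                 regionTotals = "numeric"),
  validity = function(object) {
    msg <- character()
    m <- object@matrix
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (length(object@residues) != nrow(m))
      msg <- c(msg, "'residues' must label every matrix row")
    if (nrow(m) && max(abs(m - t(m))) > 1e-8)
      msg <- c(msg, "matrix must be symmetric")
    if (nrow(m) && max(abs(diag(m) - 1)) > 1e-8)
      msg <- c(msg, "matrix diagonal must be 1")
    if (nrow(m) && max(abs(m)) > 1 + 1e-8)
      msg <- c(msg, "matrix entries must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' Lower-triangular activity-modulation matrix
#'
#' Diagonal cells hold the symmetric modulation Delta_symm of homodimer
#' activity relative to WT; off-diagonal cells hold the asymmetric
#' modulation Delta_asymm of the deconvolved heterodimer relative to its
#' 1:2:1 mixture. The upper triangle is undefined (NA).
#'
#' @slot labels ordered subunit-variant labels
#' @slot values lower-triangular Delta matrix (upper triangle NA)
#' @slot errors propagated standard deviations, same layout
#' @export
setClass("DeltaMatrix",
  representation(labels = "character", values = "matrix", errors = "matrix"),
  validity = function(object) {
    msg <- character()
    k <- length(object@labels)
    if (!all(dim(object@values) == k) || !all(dim(object@errors) == k))
      msg <- c(msg, "matrices must be k x k for k labels")
    if (k > 1 && any(!is.na(object@values[upper.tri(object@values)])))
      msg <- c(msg, "upper triangle must be NA")
    if (any(object@values[!is.na(object@values)] < -1))
      msg <- c(msg, "Delta values must be >= -1")
    if (length(msg)) msg else TRUE
  })

#' Define a contiguous protein region by residue range
#'
#' Known regions of the Hsp90 N-terminal ATPase domain include the
#' N-terminal beta-strap (residues 1-8), helix 1 (residues 9-22) and the
#' ATP gate (residues 94-125).
#'
#' @param name region name
#' @param first,last inclusive residue-number range
#' @return a `Region` object
#' @examples
#' helix1 <- Region("helix1", 9, 22)
#' @export
Region <- function(name, first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || last < first)
    stop("invalid residue range for region '", name, "'")
  new("Region", name = as.character(name),
      residues = seq.int(first, last))
}

#' @rdname Region
#' @slot name region name
#' @slot residues integer residue numbers in the region
#' @export
setClass("Region",
  representation(name = "character", residues = "integer"),
  validity = function(object) {
    if (!length(object@residues)) "region must contain residues" else TRUE
  })
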