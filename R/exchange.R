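# Closed-form two-state fast-exchange relaxation model.
#
# R2(nu) = R2,0 + (Rex/kex) * [1 - (4 nu / kex) * tanh(kex / (4 nu))]
#
# with Rex = pA * pB * dOmega^2 (rad^2 s^-2), so Rex/kex carries units of
# s^-1.  R2(nu) decreases monotonically from R2,0 + Rex/kex (nu -> 0) to
# R2,0 (nu -> infinity).

# Series threshold for x = kex/(4 nu): below this, 1 - tanh(x)/x is
# evaluated as x^2/3 - 2 x^4/15 to avoid catastrophic cancellation.
.SERIES_X <- 1e-4

.dispersionShape <- function(x) {
  # 1 - tanh(x)/x, the dimensionless dispersion shape in x = kex/(4 nu)
  out <- numeric(length(x))
  small <- x < .SERIES_X
  out[small] <- x[small]^2 / 3 - 2 * x[small]^4 / 15
  out[!small] <- 1 - tanh(x[!small]) / x[!small]
  out
}

#' Effective transverse relaxation rate under two-state fast exchange
#'
#' Evaluates the fast-exchange dispersion model
#' \deqn{R_2(\nu) = R_{2,0} + \frac{R_{ex}}{k_{ex}}\left[1 -
#'   \frac{4\nu}{k_{ex}}\tanh\!\left(\frac{k_{ex}}{4\nu}\right)\right]}
#' where \eqn{\nu} is the CPMG field strength \eqn{1/(4\tau_{CPMG})}.
#' The curve is non-increasing in \eqn{\nu}, relaxing from the
#' low-frequency plateau \eqn{R_{2,0} + R_{ex}/k_{ex}} to \eqn{R_{2,0}}
#' at fast pulsing.
#'
#' @param params a [FastExchangeParams-class] object
#' @param nu CPMG field strength(s), Hz; must be > 0
#' @return effective R2 value(s), 1/s
#' @examples
#' p <- FastExchangeParams(r2_0 = 20, rex = 16000, kex = 2000)
#' r2FastExchange(p, c(50, 200, 1000))
#' @export
r2FastExchange <- function(params, nu) {
  stopifnot(is(params, "FastExchangeParams"))
  validObject(params)
  if (any(!is.finite(nu)) || any(nu <= 0))
    stop("CPMG field strengths 'nu' must be finite and > 0")
  x <- params@kex / (4 * nu)
  params@r2_0 + (params@rex / params@kex) * .dispersionShape(x)
}

#' Exchange amplitude from populations and shift difference
#'
#' Computes \eqn{R_{ex} = p_A p_B \Delta\omega^2}, the amplitude of the
#' exchange contribution in the fast limit.  Symmetric under swapping the
#' two states, and maximal at equal populations for a fixed shift
#' difference.
#'
#' @param pop a [TwoStatePopulations-class] object (deltaOmega in rad/s)
#' @return exchange amplitude, rad^2/s^2
#' @examples
#' rexFromPopulations(TwoStatePopulations(pA = 0.9, deltaOmega = 500))
#' @export
rexFromPopulations <- function(pop) {
  stopifnot(is(pop, "TwoStatePopulations"))
  validObject(pop)
  pop@pA * pop@pB * pop@deltaOmega^2
}

#' Excited-state population from an exchange-averaged chemical shift
#'
#' In fast exchange a single resonance appears at the population-weighted
#' average shift \eqn{\delta_{obs} = p_A\delta_A + p_B\delta_B}; inverting
#' gives \eqn{p_B = (\delta_{obs} - \delta_A)/(\delta_B - \delta_A)}.
#' Used, e.g., to read the clamp-closed population from the weighted 19F
#' shift after AMP-PNP addition.
#'
#' @param deltaObs observed shift, ppm
#' @param deltaA,deltaB reference shifts of the pure states, ppm; must
#'   differ
#' @return excited-state (state B) population as a fraction.  A value
#'   outside [0, 1] signals model inconsistency: a warning is raised and
#'   the value returned with attribute `outside_range = TRUE`.
#' @examples
#' populationFromShift(-60.60, deltaA = -60.0, deltaB = -61.0)  # 0.60
#' @export
populationFromShift <- function(deltaObs, deltaA, deltaB) {
  if (deltaA == deltaB)
    stop("degenerate reference shifts: deltaA == deltaB")
  pB <- (deltaObs - deltaA) / (deltaB - deltaA)
  if (pB < 0 || pB > 1) {
    warning("population outside [0, 1]: weighted-average model inconsistent",
            call. = FALSE)
    attr(pB, "outside_range") <- TRUE
  }
  pB
}

#' Exchange-averaged chemical shift
#'
#' The population-weighted average \eqn{p_A\delta_A + p_B\delta_B} seen
#' as a single resonance in the fast-exchange limit.  Exact inverse of
#' [populationFromShift()].
#'
#' @param pop a [TwoStatePopulations-class] object
#' @param deltaA,deltaB pure-state shifts, ppm
#' @return observed shift, ppm
#' @export
exchangeAveragedShift <- function(pop, deltaA, deltaB) {
  stopifnot(is(pop, "TwoStatePopulations"))
  validObject(pop)
  pop@pA * deltaA + pop@pB * deltaB
}

#' Convert chemical shifts between ppm and angular frequency
#'
#' \eqn{\Delta\omega} [rad/s] = \eqn{2\pi} x field [MHz] x shift [ppm].
#' The default field is 657 MHz, the 19F Larmor frequency of the
#' dispersion measurements.
#'
#' @param ppm shift difference, ppm
#' @param radSec shift difference, rad/s
#' @param fieldMHz Larmor frequency of the observed nucleus, MHz
#' @return the converted shift difference
#' @examples
#' ppmToRadSec(1, fieldMHz = 657)    # 2*pi*657e6*1e-6
#' @export
ppmToRadSec <- function(ppm, fieldMHz = 657) {
  2 * pi * fieldMHz * ppm
}

#' @rdname ppmToRadSec
#' @export
radSecToPpm <- function(radSec, fieldMHz = 657) {
  radSec / (2 * pi * fieldMHz)
}

#' Convert between the two Rex conventions
#'
#' `rexPlateau()` expresses the exchange contribution as the dispersion
#' plateau height \eqn{R_{ex}/k_{ex}} in 1/s (the "Rex as plateau"
#' convention some analyses report); `rexAmplitude()` converts a plateau
#' back to the amplitude convention \eqn{p_A p_B \Delta\omega^2} in
#' rad^2/s^2 used throughout this package.
#'
#' @param rex exchange amplitude, rad^2/s^2
#' @param plateau dispersion plateau height, 1/s
#' @param kex exchange rate constant, 1/s
#' @return the converted quantity
#' @export
rexPlateau <- function(rex, kex) {
  if (kex <= 0) stop("'kex' must be > 0")
  rex / kex
}

#' @rdname rexPlateau
#' @export
rexAmplitude <- function(plateau, kex) {
  if (kex <= 0) stop("'kex' must be > 0")
  plateau * kex
}
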