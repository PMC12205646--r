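# NADH-coupled ATPase assay analysis: rate extraction from progress
# curves, inhibited-background subtraction, WT normalization, 1:2:1
# mixture deconvolution, and the Delta_symm / Delta_asymm modulation
# matrix.

#' Extract an ATP turnover rate from a progress curve
#'
#' ATP hydrolysis is read out as NADH depletion at 340 nm; the turnover
#' rate is \eqn{-slope(A_{340}\,vs\,t)/\varepsilon_{NADH}} converted to
#' \eqn{\mu M} ATP per minute and normalized by the Hsp90 dimer
#' concentration.  Unless a window is supplied, the fit uses the largest
#' initial stretch of the curve with linear-fit \eqn{R^2 \ge 0.98}
#' (minimum 5 points), which avoids the curvature that appears once NADH
#' runs low; when no initial stretch meets the threshold (e.g. a flat,
#' noise-dominated trace where \eqn{R^2} is uninformative) the full
#' curve is used.
#'
#' @param time time points, minutes
#' @param a340 path-corrected absorbances at 340 nm
#' @param hsp90Conc Hsp90 dimer concentration, uM; must be > 0
#' @param window optional `c(tmin, tmax)` restricting the fit
#' @param epsilonNADH NADH extinction coefficient, 1/(M cm); default 6220
#'   at 340 nm with a 1 cm (path-corrected) cell
#' @param r2Min linearity threshold for automatic window selection
#' @return rate in uM ATP / min / uM dimer, with attributes `slope`
#'   (A340/min), `windowPoints` and `r2`.  A significantly positive
#'   slope (A340 increasing) raises an assay-anomaly warning and returns
#'   the (negative) rate unclamped; clamping happens at background
#'   subtraction.
#' @export
rateFromCurve <- function(time, a340, hsp90Conc, window = NULL,
                          epsilonNADH = 6220, r2Min = 0.98) {
  if (length(time) != length(a340)) stop("'time'/'a340' length mismatch")
  if (hsp90Conc <= 0) stop("'hsp90Conc' must be > 0")
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; a340 <- a340[keep]
  }
  n <- length(time)
  if (n < 5L) stop("need >= 5 points in the fitting window")
  ord <- order(time)
  time <- time[ord]; a340 <- a340[ord]

  linStat <- function(k) {
    tk <- time[1:k]; ak <- a340[1:k]
    tc <- tk - mean(tk)
    sxx <- sum(tc^2)
    slope <- sum(tc * ak) / sxx
    res <- ak - mean(ak) - slope * tc
    ss <- sum((ak - mean(ak))^2)
    r2 <- if (ss <= .Machine$double.eps * k) 1 else 1 - sum(res^2) / ss
    se <- sqrt(sum(res^2) / (k - 2) / sxx)
    list(slope = slope, se = se, r2 = r2)
  }
  kUse <- n; st <- linStat(n)
  if (is.null(window) && st$r2 < r2Min) {
    for (k in seq(n - 1, 5)) {
      cand <- linStat(k)
      if (cand$r2 >= r2Min) { kUse <- k; st <- cand; break }
    }
    # no initial stretch linear enough: keep the full curve
    if (st$r2 < r2Min) { kUse <- n; st <- linStat(n) }
  }
  slope <- st$slope
  slopeSE <- st$se
  if (is.finite(slopeSE) && slopeSE > 0 && slope > 2 * slopeSE)
    warning("A340 increases significantly with time: assay anomaly",
            call. = FALSE)
  rate <- -slope / epsilonNADH * 1e6 / hsp90Conc
  attr(rate, "slope") <- slope
  attr(rate, "windowPoints") <- kUse
  attr(rate, "r2") <- st$r2
  rate
}

#' Subtract the inhibited-well background from replicate rates
#'
#' Each assay condition is paired with replicate wells in which Hsp90 is
#' inhibited (150 uM NVP-AUY922); the net Hsp90 activity is the mean
#' sample rate minus the mean inhibited rate, with replicate standard
#' deviations combined in quadrature.  A negative net rate is clamped to
#' zero with a warning (such samples lack detectable ATPase activity).
#'
#' @param sampleRates replicate rates for the active condition
#' @param inhibitedRates replicate rates for the matched inhibited wells
#' @return list with `rate`, `sd`, `nReps`
#' @export
subtractBackground <- function(sampleRates, inhibitedRates) {
  if (!length(sampleRates) || !length(inhibitedRates))
    stop("need >= 1 replicate of both sample and inhibited rates")
  net <- mean(sampleRates) - mean(inhibitedRates)
  sdS <- if (length(sampleRates) > 1) sd(sampleRates) else 0
  sdI <- if (length(inhibitedRates) > 1) sd(inhibitedRates) else 0
  if (net < 0) {
    warning("negative net rate clamped to 0 (no detectable activity)",
            call. = FALSE)
    net <- 0
  }
  list(rate = net, sd = sqrt(sdS^2 + sdI^2), nReps = length(sampleRates))
}

#' Dimer composition from a subunit mixing fraction
#'
#' Random subunit association of a 1:1 (or general `f1`) mixture of two
#' subunit species gives binomial dimer proportions
#' \eqn{(f_1^2,\; 2f_1(1-f_1),\; (1-f_1)^2)} — the 1:2:1
#' homodimer1:heterodimer:homodimer2 distribution of Pascal's triangle
#' at \eqn{f_1 = 0.5}.
#'
#' @param f1 mixing fraction of subunit 1, in [0, 1]
#' @return named numeric `(homodimer1, heterodimer, homodimer2)`,
#'   summing to 1
#' @examples
#' mixtureComposition(0.5)  # 0.25 0.50 0.25
#' @export
mixtureComposition <- function(f1 = 0.5) {
  if (!is.finite(f1) || f1 < 0 || f1 > 1) stop("'f1' must lie in [0, 1]")
  c(homodimer1 = f1^2, heterodimer = 2 * f1 * (1 - f1),
    homodimer2 = (1 - f1)^2)
}

#' Deconvolve pure heterodimer activity from a 1:2:1 mixture
#'
#' Inverts the composition-weighted mixture mean: the observed activity
#' of a 1:2:1 homodimer1:heterodimer:homodimer2 mixture is
#' \eqn{0.25\,homD1 + 0.5\,hetD + 0.25\,homD2}, so
#' \deqn{hetD = \frac{homhetmix - 0.25\,homD1 - 0.25\,homD2}{0.5}}
#' All activities are on the fraction-of-WT scale.
#'
#' @param homhetmix observed fractional activity of the 1:2:1 mixture
#' @param homd1,homd2 fractional activities of the two pure homodimers
#' @return fractional WT activity of the pure heterodimer
#' @examples
#' heterodimerActivity(1.6, 0, 2.5)  # 1.95
#' @export
heterodimerActivity <- function(homhetmix, homd1, homd2) {
  if (any(!is.finite(c(homhetmix, homd1, homd2))))
    stop("activities must be finite")
  (homhetmix - (0.25 * homd1 + 0.25 * homd2)) / 0.5
}

#' Asymmetric activity modulation
#'
#' The difference between the deconvolved pure-heterodimer activity and
#' the activity measured for its 1:2:1 mixture,
#' \eqn{\Delta_{asymm} = hetD - homhetmix}; positive when the
#' heterodimer is stimulated beyond the mixture, negative when
#' repressed, bounded below by -1.
#'
#' @param hetd deconvolved heterodimer fractional activity
#' @param homhetmix measured 1:2:1 mixture fractional activity
#' @return Delta_asymm, dimensionless
#' @examples
#' deltaAsymm(1.95, 1.6)  # +0.35
#' @export
deltaAsymm <- function(hetd, homhetmix) {
  if (any(!is.finite(c(hetd, homhetmix)))) stop("inputs must be finite")
  hetd - homhetmix
}

#' Symmetric activity modulation
#'
#' The change in fractional WT ATPase activity of a homodimer relative
#' to WT, \eqn{\Delta_{symm} = homD - WT} with WT normalized to 1; 0 for
#' WT itself, -1 for a fully repressed homodimer.
#'
#' @param homd homodimer fractional WT activity
#' @param wt normalized WT activity (1 by convention)
#' @return Delta_symm, dimensionless
#' @examples
#' deltaSymm(2.5)  # +1.5
#' @export
deltaSymm <- function(homd, wt = 1) {
  if (any(!is.finite(c(homd, wt)))) stop("inputs must be finite")
  homd - wt
}

#' Cochaperone fold-stimulation of ATP turnover
#'
#' Ratio of net (background-subtracted) rates with and without the
#' cochaperone (e.g. Aha1).  Undefined when the basal rate is zero or
#' indistinguishable from zero, as for catalytically dead homodimers.
#'
#' @param ratePlus net rate with the cochaperone
#' @param rateMinus net basal rate
#' @param minRate smallest basal rate considered nonzero
#' @return fold stimulation (dimensionless)
#' @export
foldStimulation <- function(ratePlus, rateMinus, minRate = 1e-6) {
  if (!is.finite(rateMinus) || rateMinus <= minRate)
    stop("fold stimulation undefined: basal rate is zero or near zero")
  ratePlus / rateMinus
}

#' Assemble the lower-triangular activity-modulation matrix
#'
#' Diagonal cells report \eqn{\Delta_{symm}} for each homodimer;
#' off-diagonal lower-triangle cells report \eqn{\Delta_{asymm}} for
#' each measured subunit pair, obtained by deconvolving the pair's 1:2:1
#' mixture with [heterodimerActivity()].  Pairs without a measured
#' mixture — or whose constituent homodimer references are missing — are
#' left NA (never zero), with the missing-reference cases listed in the
#' returned object's `issues` attribute.  Replicate SDs are propagated
#' to first order: \eqn{sd(\Delta_{asymm})^2 = sd_{mix}^2 +
#' 0.25\,sd_{h1}^2 + 0.25\,sd_{h2}^2}.
#'
#' @param records data.frame with columns `subunit1`, `subunit2`,
#'   `fractional_wt`, and optionally `fractional_sd`; rows with
#'   `subunit1 == subunit2` are homodimers, others are 1:2:1 mixtures
#' @param labels optional ordering of subunit variants (default: order
#'   of first appearance)
#' @return a [DeltaMatrix-class]
#' @export
buildDeltaMatrix <- function(records, labels = NULL) {
  req <- c("subunit1", "subunit2", "fractional_wt")
  if (!all(req %in% names(records)))
    stop("records need columns: ", paste(req, collapse = ", "))
  if (!"fractional_sd" %in% names(records)) records$fractional_sd <- 0
  if (is.null(labels))
    labels <- unique(c(rbind(records$subunit1, records$subunit2)))
  k <- length(labels)
  vals <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  errs <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  issues <- character()
  homo <- records[records$subunit1 == records$subunit2, , drop = FALSE]
  getHomo <- function(lab) {
    i <- match(lab, homo$subunit1)
    if (is.na(i)) NULL else homo[i, ]
  }
  for (i in seq_len(k)) {
    h <- getHomo(labels[i])
    if (!is.null(h)) {
      vals[i, i] <- deltaSymm(h$fractional_wt)
      errs[i, i] <- h$fractional_sd
    }
  }
  mix <- records[records$subunit1 != records$subunit2, , drop = FALSE]
  for (r in seq_len(nrow(mix))) {
    i <- match(mix$subunit1[r], labels)
    j <- match(mix$subunit2[r], labels)
    if (is.na(i) || is.na(j)) next
    lo <- max(i, j); hi <- min(i, j)   # lower triangle cell
    h1 <- getHomo(mix$subunit1[r]); h2 <- getHomo(mix$subunit2[r])
    if (is.null(h1) || is.null(h2)) {
      issues <- c(issues, sprintf(
        "%s:%s mixture lacks a homodimer reference",
        mix$subunit1[r], mix$subunit2[r]))
      next
    }
    hetd <- heterodimerActivity(mix$fractional_wt[r], h1$fractional_wt,
                                h2$fractional_wt)
    vals[lo, hi] <- deltaAsymm(hetd, mix$fractional_wt[r])
    errs[lo, hi] <- sqrt(mix$fractional_sd[r]^2 +
                           0.25 * h1$fractional_sd^2 +
                           0.25 * h2$fractional_sd^2)
  }
  out <- new("DeltaMatrix", labels = labels, values = vals, errors = errs)
  attr(out, "issues") <- issues
  out
}

#' Compute background-subtracted, WT-normalized activities from a plate
#'
#' Runs the full plate pipeline: extracts a rate from every well
#' ([rateFromCurve()]), averages replicates per sample, subtracts the
#' matched inhibited-well background ([subtractBackground()]), and
#' normalizes to the WT homodimer net rate.
#'
#' @param plate long-format data.frame: `well_id`, `time_min`, `a340`
#' @param wellmap data.frame: `well_id`, `sample_label`, `subunit1`,
#'   `subunit2`, `inhibited` (0/1), `aha1` (0/1), `hsp90_um`, `replicate`
#' @param wtLabel subunit label of the WT reference (both subunits)
#' @param ... passed to [rateFromCurve()]
#' @return data.frame with one row per non-inhibited sample:
#'   `sample_label`, `subunit1`, `subunit2`, `aha1`, `rate`, `rate_sd`
#'   (replicate SD, the error-bar convention of the assay), `n_reps`,
#'   `fractional_wt` and `fractional_sd` (standard error of the
#'   replicate-mean fractional activity, `rate_sd / sqrt(n_reps) / WT`;
#'   the uncertainty carried into Delta-matrix propagation)
#' @export
plateActivities <- function(plate, wellmap, wtLabel = "WT", ...) {
  req <- c("well_id", "time_min", "a340")
  if (!all(req %in% names(plate))) stop("plate needs columns: ",
                                        paste(req, collapse = ", "))
  reqm <- c("well_id", "sample_label", "subunit1", "subunit2", "inhibited",
            "hsp90_um")
  if (!all(reqm %in% names(wellmap))) stop("wellmap needs columns: ",
                                           paste(reqm, collapse = ", "))
  if (!"aha1" %in% names(wellmap)) wellmap$aha1 <- 0
  rates <- vapply(seq_len(nrow(wellmap)), function(i) {
    w <- plate[plate$well_id == wellmap$well_id[i], , drop = FALSE]
    if (!nrow(w)) return(NA_real_)
    as.numeric(rateFromCurve(w$time_min, w$a340, wellmap$hsp90_um[i], ...))
  }, numeric(1))
  wellmap$.rate <- rates
  key <- interaction(wellmap$sample_label, wellmap$aha1, drop = TRUE)
  out <- do.call(rbind, lapply(split(wellmap, key), function(g) {
    samp <- g$.rate[g$inhibited == 0 & !is.na(g$.rate)]
    inhib <- g$.rate[g$inhibited == 1 & !is.na(g$.rate)]
    if (!length(samp)) return(NULL)
    if (!length(inhib)) inhib <- 0   # no inhibited wells: assume none
    net <- suppressWarnings(subtractBackground(samp, inhib))
    data.frame(sample_label = g$sample_label[1], subunit1 = g$subunit1[1],
               subunit2 = g$subunit2[1], aha1 = g$aha1[1],
               rate = net$rate, rate_sd = net$sd, n_reps = net$nReps,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  wt <- out$rate[out$subunit1 == wtLabel & out$subunit2 == wtLabel &
                   out$aha1 == 0]
  if (length(wt) != 1 || !is.finite(wt) || wt <= 0)
    stop("WT normalization failed: no usable '", wtLabel, ":", wtLabel,
         "' homodimer reference on the plate")
  out$fractional_wt <- out$rate / wt
  out$fractional_sd <- out$rate_sd / sqrt(out$n_reps) / wt
  out
}

#' Aha1 fold-stimulation table from a plate activity table
#'
#' Pairs each +Aha1 sample with its matched basal sample (same subunit
#' pair) and reports the fold stimulation; samples whose basal rate is
#' zero get NA with an explanatory note (fold undefined).
#'
#' @param activities output of [plateActivities()]
#' @param minRate passed to [foldStimulation()]
#' @return data.frame `subunit1`, `subunit2`, `fold`, `note`
#' @export
aha1FoldTable <- function(activities, minRate = 1e-6) {
  plus <- activities[activities$aha1 == 1, , drop = FALSE]
  if (!nrow(plus)) return(data.frame(subunit1 = character(),
                                     subunit2 = character(),
                                     fold = numeric(), note = character()))
  base <- activities[activities$aha1 == 0, , drop = FALSE]
  out <- lapply(seq_len(nrow(plus)), function(i) {
    j <- which(base$subunit1 == plus$subunit1[i] &
                 base$subunit2 == plus$subunit2[i])
    fold <- NA_real_; note <- ""
    if (!length(j)) note <- "no matched basal sample"
    else fold <- tryCatch(
      foldStimulation(plus$rate[i], base$rate[j[1]], minRate),
      error = function(e) { note <<- conditionMessage(e); NA_real_ })
    data.frame(subunit1 = plus$subunit1[i], subunit2 = plus$subunit2[i],
               fold = fold, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
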