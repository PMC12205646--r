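# Kabsch superposition, dynamical cross-correlation matrices, and
# region-restricted total-correlation sums.

.selectAtoms <- function(window, residues = NULL, atoms = NULL) {
  keep <- rep(TRUE, nrow(window@atomIndex))
  if (!is.null(residues)) {
    if (is(residues, "Region")) residues <- residues@residues
    keep <- keep & window@atomIndex$resno %in% residues
  }
  if (!is.null(atoms)) keep <- keep & window@atomIndex$elety %in% atoms
  which(keep)
}

# optimal rotation/translation mapping P onto Q (both n x 3), Kabsch
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

#' Superpose trajectory frames onto a reference
#'
#' Rigid-body (Kabsch) least-squares superposition of every frame onto a
#' reference frame, fitting on a selection of atoms (by default the main
#' chain N, CA and C atoms, the selection used to align residues 4-207
#' before cross-correlation analysis) and applying the transform to all
#' atoms.  The fit-selection RMSD after superposition is never larger
#' than before, and frames differing from the reference by a pure rigid
#' motion come out exactly on top of it.
#'
#' @param window a [TrajectoryWindow-class]
#' @param residues fit-selection residues: integer vector or a
#'   [Region()]; NULL selects all residues
#' @param atoms fit-selection atom names; NULL selects all atoms
#' @param reference index of the reference frame (default 1)
#' @return the superposed [TrajectoryWindow-class], with per-frame
#'   fit-selection RMSDs (Angstrom) in attribute `rmsd`
#' @export
superpose <- function(window, residues = NULL, atoms = c("N", "CA", "C"),
                      reference = 1L) {
  stopifnot(is(window, "TrajectoryWindow"))
  validObject(window)
  sel <- .selectAtoms(window, residues, atoms)
  if (length(sel) < 3L)
    stop("underdetermined superposition: fewer than 3 fit atoms")
  co <- window@coords
  nf <- dim(co)[1]
  ref <- co[reference, sel, , drop = TRUE]
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    P <- co[f, sel, , drop = TRUE]
    k <- .kabsch(P, ref)
    allf <- co[f, , , drop = TRUE]
    co[f, , ] <- sweep(sweep(allf, 2, k$cp) %*% t(k$R), 2, k$cq, "+")
    fitted <- co[f, sel, , drop = TRUE]
    rmsd[f] <- sqrt(mean(rowSums((fitted - ref)^2)))
  }
  out <- initialize(window, coords = co)
  attr(out, "rmsd") <- rmsd
  out
}

#' Dynamical cross-correlation matrix of CA displacements
#'
#' For each selected atom the displacement from its mean position,
#' \eqn{\Delta r_i(t) = r_i(t) - \langle r_i\rangle}, is correlated with
#' every other atom's:
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle|\Delta r_i|^2\rangle\,\langle|\Delta r_j|^2\rangle}}}
#' The matrix is symmetric with unit diagonal and entries in [-1, 1];
#' +1 marks perfectly correlated motion, -1 perfectly anticorrelated.
#' The window must already be superposed (see [superpose()]) or the
#' matrix will mix internal motion with global tumbling.
#'
#' @param window a superposed [TrajectoryWindow-class]
#' @param residues residues to include (integer vector or [Region()];
#'   default all)
#' @param atoms atom name(s) used per residue; default "CA"
#' @return a [DCCMResult-class]
#' @export
computeDCCM <- function(window, residues = NULL, atoms = "CA") {
  stopifnot(is(window, "TrajectoryWindow"))
  validObject(window)
  sel <- .selectAtoms(window, residues, atoms)
  if (!length(sel)) stop("selection matches no atoms")
  nf <- dim(window@coords)[1]
  if (nf < 10L)
    warning("fewer than 10 frames: correlations will be noisy",
            call. = FALSE)
  X <- window@coords[, sel, 1, drop = TRUE]
  Y <- window@coords[, sel, 2, drop = TRUE]
  Z <- window@coords[, sel, 3, drop = TRUE]
  cen <- function(M) sweep(M, 2, colMeans(M))
  X <- cen(X); Y <- cen(Y); Z <- cen(Z)
  covm <- (crossprod(X) + crossprod(Y) + crossprod(Z)) / nf
  v <- diag(covm)
  if (any(v <= 0)) {
    bad <- window@atomIndex$resno[sel][which(v <= 0)]
    stop("zero-variance atom(s) at residue(s): ",
         paste(unique(bad), collapse = ", "))
  }
  C <- covm / sqrt(outer(v, v))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  resnos <- as.integer(window@atomIndex$resno[sel])
  dimnames(C) <- list(resnos, resnos)
  new("DCCMResult", matrix = C, residues = resnos,
      regionTotals = setNames(numeric(0), character(0)))
}

#' Region-restricted total correlation
#'
#' Sums the off-diagonal cross-correlations between two residue regions,
#' counting each unordered residue pair exactly once (so the symmetric
#' upper and lower triangles are never double-counted) and never
#' including diagonal elements.  For a region against itself this is the
#' sum over the \eqn{n(n-1)/2} within-region pairs; residues shared by
#' two overlapping regions likewise contribute each pair once.
#'
#' @param dccm a [DCCMResult-class]
#' @param regionA,regionB [Region()] objects (or integer residue
#'   vectors)
#' @return the summed correlation, dimensionless
#' @examples
#' ## helix 1 against the ATP gate:
#' ## totalCorrelation(dccm, Region("helix1", 9, 22),
#' ##                  Region("gate", 94, 125))
#' @export
totalCorrelation <- function(dccm, regionA, regionB = regionA) {
  stopifnot(is(dccm, "DCCMResult"))
  resA <- if (is(regionA, "Region")) regionA@residues else
    as.integer(regionA)
  resB <- if (is(regionB, "Region")) regionB@residues else
    as.integer(regionB)
  iA <- which(dccm@residues %in% resA)
  iB <- which(dccm@residues %in% resB)
  if (!length(iA) || !length(iB))
    stop("region has no residues in the correlation matrix")
  n <- nrow(dccm@matrix)
  inA <- seq_len(n) %in% iA
  inB <- seq_len(n) %in% iB
  pairMask <- (outer(inA, inB, "&") | outer(inB, inA, "&"))
  diag(pairMask) <- FALSE
  sum(dccm@matrix[pairMask & upper.tri(pairMask)])
}

#' Attach named region-pair totals to a DCCM result
#'
#' @param dccm a [DCCMResult-class]
#' @param regions named list of [Region()] objects
#' @param pairs optional 2-column character matrix of region-name pairs;
#'   default: all unordered pairs including each region with itself
#' @return the [DCCMResult-class] with `regionTotals` filled, named
#'   "A|B"
#' @export
regionTotalTable <- function(dccm, regions, pairs = NULL) {
  stopifnot(is(dccm, "DCCMResult"))
  nms <- vapply(regions, function(r) r@name, character(1))
  names(regions) <- nms
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(length(nms)), diag = TRUE), arr.ind = TRUE)
    pairs <- cbind(nms[idx[, "row"]], nms[idx[, "col"]])
  }
  totals <- apply(pairs, 1, function(pr)
    totalCorrelation(dccm, regions[[pr[1]]], regions[[pr[2]]]))
  initialize(dccm,
             regionTotals = setNames(totals,
                                     paste(pairs[, 1], pairs[, 2],
                                           sep = "|")))
}

#' Windowed DCCM series over a trajectory
#'
#' Subsamples the trajectory at `stepNs` and computes one DCCM per
#' window of length `windowNs`.  The default placement is the single
#' window covering the final `windowNs` of the trajectory — the
#' 10 ns-step / 800 ns-window sampling used for a 1 us production run —
#' with `tile = TRUE` producing non-overlapping windows from the start
#' instead.  Each window is superposed on its own first frame before
#' correlation.
#'
#' @param traj a [TrajectoryWindow-class] holding the full trajectory
#' @param stepNs analysis frame spacing, ns; must be a multiple of the
#'   trajectory's frame spacing and <= `windowNs`
#' @param windowNs window length, ns
#' @param fitResidues,fitAtoms superposition selection (see
#'   [superpose()])
#' @param residues,atoms correlation selection (see [computeDCCM()])
#' @param tile FALSE: one final window; TRUE: non-overlapping windows
#' @return list of [DCCMResult-class], one per window, with window start
#'   times (ns) as names
#' @export
windowedDCCM <- function(traj, stepNs = 10, windowNs = 800,
                         fitResidues = NULL, fitAtoms = c("N", "CA", "C"),
                         residues = NULL, atoms = "CA", tile = FALSE) {
  stopifnot(is(traj, "TrajectoryWindow"))
  validObject(traj)
  if (stepNs > windowNs) stop("'stepNs' must not exceed 'windowNs'")
  sp <- traj@frameSpacing
  if (abs(stepNs / sp - round(stepNs / sp)) > 1e-8)
    stop("'stepNs' must be a multiple of the stored frame spacing")
  every <- as.integer(round(stepNs / sp))
  nf <- dim(traj@coords)[1]
  span <- (nf - 1) * sp
  if (span < windowNs) stop("trajectory shorter than one window")
  perWin <- as.integer(floor(windowNs / stepNs)) + 1L
  starts <- if (tile) {
    seq(1L, nf - (perWin - 1L) * every, by = (perWin - 1L) * every + every)
  } else {
    nf - (perWin - 1L) * every
  }
  out <- lapply(starts, function(s) {
    idx <- s + every * (seq_len(perWin) - 1L)
    sub <- TrajectoryWindow(traj@coords[idx, , , drop = FALSE],
                            traj@atomIndex, frameSpacing = stepNs)
    sub <- superpose(sub, residues = fitResidues, atoms = fitAtoms)
    computeDCCM(sub, residues = residues, atoms = atoms)
  })
  names(out) <- (starts - 1L) * sp
  out
}
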