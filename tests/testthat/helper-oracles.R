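# Independent oracles, implemented from first principles and kept
# deliberately naive so they share no code path with the package.

# tanh evaluated through term-by-term Taylor series of sinh and cosh
# (both converge for all x), to machine precision; above x = 19 the
# series overflows and tanh is evaluated from exp instead (still
# independent of the base tanh).
tanhSeries <- function(x) {
  if (x > 19) return((1 - exp(-2 * x)) / (1 + exp(-2 * x)))
  sinhT <- 0; coshT <- 0
  term <- x  # x^(2k+1)/(2k+1)! starting at k = 0
  k <- 0
  repeat {
    sinhT <- sinhT + term
    cterm <- term * (2 * k + 1) / x   # x^(2k)/(2k)!
    coshT <- coshT + cterm
    k <- k + 1
    term <- term * x^2 / ((2 * k) * (2 * k + 1))
    if (abs(term) < 1e-18 * abs(sinhT)) break
  }
  sinhT / coshT
}

# fast-exchange dispersion model evaluated with the series tanh
oracleR2 <- function(r2_0, rexAmp, kexRate, nu) {
  x <- kexRate / (4 * nu)
  r2_0 + (rexAmp / kexRate) * (1 - tanhSeries(x) / x)
}

# brute-force DCCM: explicit double loop over atoms and frames
bruteDCCM <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  C <- matrix(NA_real_, na, na)
  for (i in seq_len(na)) for (j in seq_len(na)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(nf)) {
      di <- coords[f, i, ] - mu[i, ]
      dj <- coords[f, j, ] - mu[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di)
      vj <- vj + sum(dj * dj)
    }
    C[i, j] <- num / sqrt(vi * vj)
  }
  C
}

# brute-force total correlation: enumerate every unordered residue pair
bruteTotalCorrelation <- function(mat, residues, regA, regB) {
  tot <- 0
  n <- length(residues)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next   # each unordered pair once, no diagonal
    inPair <- (residues[i] %in% regA && residues[j] %in% regB) ||
      (residues[i] %in% regB && residues[j] %in% regA)
    if (inPair) tot <- tot + mat[i, j]
  }
  tot
}

# small deterministic dispersion parameter grid for property tests
paramGrid <- function() {
  expand.grid(r2_0 = c(5, 25, 60), plateau = c(0.5, 8, 40),
              kex = c(200, 1500, 2e4, 3e5))
}
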