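---
title: "Quantifying Hsp90 clamp-cycle dynamics: models, estimators, and design choices"
author: "hsp90dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Hsp90 clamp-cycle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsp90dyn)
```

Hsp90 is a dimeric, ATP-driven chaperone whose N-terminal ATPase domains
cycle between an open, catalytically inactive conformation and a closed,
compact "clamp" state. Three observables report on that cycle, and this
package implements the quantitative analysis of each: microsecond--millisecond
conformational exchange seen by ¹⁹F CPMG relaxation dispersion and lineshape
analysis; steady-state ATP turnover of homodimers and subunit-mixed
heterodimers in an NADH-coupled assay; and correlated inter-region motions in
molecular dynamics trajectory windows. A synthetic-data layer generates every
input class with known ground truth, so the entire pipeline is testable
without any measured data.

# Two-state fast exchange

## Model

A ¹⁹F reporter exchanging rapidly between two conformations relaxes with an
effective rate that depends on the CPMG pulsing frequency
$\nu_{CPMG} = 1/(4\tau_{CPMG})$:

$$R_2(\nu) = R_{2,0} + \frac{R_{ex}}{k_{ex}}
  \left[1 - \frac{4\nu}{k_{ex}}\tanh\frac{k_{ex}}{4\nu}\right]$$

with the exchange amplitude formally $R_{ex} = p_A p_B \Delta\omega^2$
(rad²·s⁻²). The curve decays monotonically from the slow-pulsing plateau
$R_{2,0} + R_{ex}/k_{ex}$ to $R_{2,0}$. Two conventions for the exchange
term circulate: the amplitude convention used here (rad²·s⁻², so
$R_{ex}/k_{ex}$ has units of s⁻¹) and a "plateau" convention that quotes
$R_{ex}/k_{ex}$ directly in s⁻¹. `rexPlateau()` and `rexAmplitude()` convert
between them, and `ppmToRadSec()` converts shift differences at a given
spectrometer frequency (default 657 MHz, the ¹⁹F field of the dispersion
data).

Numerically, $1 - \tanh(x)/x$ with $x = k_{ex}/(4\nu)$ suffers catastrophic
cancellation as $x \to 0$; below $x = 10^{-4}$ it is evaluated by its series
$x^2/3 - 2x^4/15$, which keeps the relative error below the noise floor set
by machine epsilon. Slow- and intermediate-exchange treatments
(Carver--Richards, Bloch--McConnell) and multi-site exchange are out of
scope by design: the data regime this package addresses is fast exchange,
where a single population-weighted resonance is observed.

## Fitting and uncertainties

`fitDispersion()` minimizes the error-weighted sum of squared residuals by
bounded Levenberg--Marquardt with a multi-start in $k_{ex}$ (five log-spaced
starts over $10^2$--$10^5$ s⁻¹). The multi-start matters: the tanh model has
shallow valleys in $k_{ex}$, and an 11-point design over 50--1000 Hz
partially aliases $(R_{2,0}, R_{ex}, k_{ex})$ against a
large-$k_{ex}$/zero-$R_{2,0}$ branch. Parameters are bounded to the physical
region $R_{2,0} > 0$, $R_{ex} \ge 0$, $k_{ex} > 0$. Temperatures are fit
independently — no Arrhenius/Eyring coupling — matching how the dispersion
series is analysed per temperature.

`monteCarloErrors()` is a parametric Monte Carlo: synthetic replicates are
drawn from the best-fit curve plus Gaussian noise (per-point errors when
available, otherwise the df-corrected residual RMS), each replicate is refit
with the full multi-start, and the parameter standard deviations over 500
draws (default; second moments are stable well below that) are reported.
Resampling around the model curve rather than around the observed points is
deliberate: re-noising observed data counts the measurement noise twice and
anchors every draw at the dataset's idiosyncratic deviation, which in pilot
simulations inflated the $R_{2,0}$ spread several-fold relative to the
spread over independently regenerated datasets. The parametric version
reproduces that ensemble spread within a factor well below two.

## Flat-versus-exchange classification

Some reporters show flat dispersion profiles (no detectable exchange), and
classifying profiles objectively requires a calibrated test.
`compareFlatVsExchange()` computes the extra-sum-of-squares F statistic
between the 1-parameter flat model and the 3-parameter exchange model. At
fixed $k_{ex}$ the exchange model is linear in the other two parameters, so
the global optimum is found exactly by profiling $k_{ex}$ over a dense log
grid (the amplitude is left unsigned here to keep the alternative a smooth
family; the physical fit keeps its bound).

The classical $F(2, n-3)$ reference is *not* used for the p-value: under a
flat truth $k_{ex}$ is unidentified and the amplitude sits on a boundary,
and simulation shows the asymptotic test rejects at only $\approx 0.02$ when
run at $\alpha = 0.05$. The reported p-value is therefore calibrated against
a Monte Carlo null — flat profiles with the data's own error structure
pushed through the identical statistic — which restores the nominal
false-positive rate (empirically $\approx 0.05$ over 1000 flat simulations).
The asymptotic p-value is still returned as `pAsymptotic`. Ties at equal SSE
prefer the flat model (parsimony).

# Lineshape, populations, and build-up

1-D spectra are modelled as sums of Lorentzians with a joint linear
baseline; a pure Lorentzian is the correct lineshape when the width is read
as a relaxation rate, $T_2 = 1/(\pi \cdot \mathrm{FWHM_{Hz}})$ (a 10 Hz line
is 31.83 ms). Voigt profiles are intentionally not offered — adding a
Gaussian component would decouple the width from $T_2$. Initial peak
positions are snapped to the local intensity maximum within ±0.1 ppm before
optimization, because ¹⁹F lines a few Hz wide at 657 MHz are only
thousandths of a ppm across and a hand-supplied guess is otherwise many
linewidths off. Whether a reported $T_2$ derives from a linewidth or an
echo-decay experiment is a genuine ambiguity of such datasets; linewidth is
the default readout here and areas are analytic Lorentzian areas.

In fast exchange the observed shift is the population-weighted average
$\delta_{obs} = p_A\delta_A + p_B\delta_B$; `populationFromShift()` inverts
it to the excited-state (e.g. clamp-closed) population and flags, but still
returns, values outside [0, 1].

Slow clamp closure after nucleotide addition is fit by
`fitBuildup()` as a single-exponential two-state build-up with one shared
rate — the clamp-closed area rising as $A_\infty(1 - e^{-k_{obs}t})$ while
the NM-state area decays toward its end level. The multi-step rate law of
AMP-PNP binding is deliberately simplified to this form and the result is
flagged as such in the output (`model` field). Detectability is decided
against a constant-areas null by an approximate F-test, which cleanly covers
both "no build-up" and "complete before the first observation" (too rapid
to be observed); in either case the fitted rate is not meaningful and
`buildupDetected` is `FALSE`.

# ATPase activities and the Δ matrix

ATP turnover is read from NADH depletion at 340 nm:
$rate = -\mathrm{slope}(A_{340})/\varepsilon_{NADH}$, scaled to
μM ATP·min⁻¹·(μM dimer)⁻¹ with $\varepsilon_{NADH} = 6220$ M⁻¹cm⁻¹ by
default (the standard 340 nm value; configurable). The fitting window is
the largest initial stretch with linear-fit $R^2 \ge 0.98$ (minimum five
points), which avoids late-curve curvature as NADH depletes without manual
gating; when no initial stretch qualifies — flat, noise-dominated traces
make $R^2$ uninformative — the full curve is used. Each condition is paired
with NVP-AUY922-inhibited wells; the net rate is the replicate-mean
difference, negative nets are clamped to zero with a warning (such samples
lack detectable activity), and activities are normalized to the WT
homodimer.

Mixing two subunit species 1:1 and letting dimers re-equilibrate yields
binomial 1:2:1 homodimer₁:heterodimer:homodimer₂ proportions
($f_1^2, 2f_1(1-f_1), (1-f_1)^2$; general $f_1$ is supported for
sensitivity analysis, and subunit-exchange equilibrium is taken as given).
The pure-heterodimer activity follows by inverting the mixture mean,

$$hetD = \frac{homhetmix - 0.25\,homD1 - 0.25\,homD2}{0.5},$$

and the two modulation statistics are
$\Delta_{asymm} = hetD - homhetmix$ and $\Delta_{symm} = homD - WT$
(WT $\equiv 1$). Worked example with the measured activity levels of a dead
strap-mutant homodimer (0), a stimulated helix-1-mutant homodimer (2.5) and
their 1.6× mixture:

```{r worked}
hetd <- heterodimerActivity(1.6, 0, 2.5)
hetd
deltaAsymm(hetd, 1.6)
deltaSymm(2.5)
```

`buildDeltaMatrix()` assembles the lower-triangular matrix (diagonal
$\Delta_{symm}$, off-diagonal $\Delta_{asymm}$); pairs without a measured
mixture or without both homodimer references stay `NA`, never zero. Error
propagation is first-order through the equations above, carried on the
standard error of the replicate mean, so Δ uncertainties shrink as
$1/\sqrt{n_{reps}}$; the per-sample `rate_sd` column keeps the plain
replicate SD, the error-bar convention of the assay. Whether the matrix is
computed from replicate means or per replicate is a free choice; replicate
means with propagated errors are the default. Aha1 fold-stimulation is the
ratio of net rates with/without the cochaperone and is reported as
undefined (not zero, not infinite) when the basal rate is zero.
Michaelis--Menten decomposition and modelling of the coupling enzymes are
out of scope: all rates assume the linear, coupling-saturated regime.

# Trajectory cross-correlations

`superpose()` performs Kabsch least-squares superposition of every frame
onto a reference (first frame by default; the analysis convention fits
main-chain N, Cα, C atoms of the structured core, residues 4–207 in the
full-length numbering). `computeDCCM()` then forms

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
  {\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}}$$

over Cα displacement vectors, and `totalCorrelation()` sums off-diagonal
elements over a region pair counting each unordered residue pair exactly
once — for a region against itself the $n(n-1)/2$ within-region pairs, for
overlapping regions each pair once, never the diagonal. Region defaults
follow the domain's functional anatomy: β-strap 1–8, helix 1 9–22, ATP gate
94–125, with helix 1 × gate the default pair of interest.

The windowed driver reads a "10 ns steps over an 800 ns window" design as
80 analysis frames, placed by default as the single window covering the
final 800 ns of a run; both step and window are configurable and a tiling
mode exists because window placement conventions vary. Residue indexing
follows the topology's own numbering with no re-indexing.

One numerical subtlety is documented rather than hidden: superposition
removes six rigid-body degrees of freedom from the displacement field, and
when collective inter-region motion projects onto those degrees of freedom
the estimated correlations attenuate toward zero. Superposition is exactly
equivariant — a rigid-motion overlay changes the aligned coordinates not at
all (to rounding), which the tests verify to $10^{-10}$ — so recovery
benchmarks are defined on windows generated in a common frame, and
superposition is applied when (and only when) frames arrive in arbitrary
orientations.

# What the generators emulate — and what they do not

Each generator draws Gaussian noise (matching the least-squares assumptions
of every fitter), records its seed, and emits a machine-readable truth
record; identical seeds give bit-identical data, and the displacement
stream of the trajectory generator is unchanged by toggling rigid motion.

* `simulateDispersion()`: model curves on the 11-point, 50–1000 Hz grid
  (the per-profile design of the dispersion experiments), iid noise of
  0.5 s⁻¹ by default.
* `simulateSpectrum()`: sums of Lorentzians from (center, $T_2$, area)
  triples at 657 MHz.
* `simulatePlate()`: linear NADH-depletion curves for a five-variant panel
  at its measured activity levels (WT 1, helix-1 mutant 2.5, strap and
  catalytic mutants 0), 1:2:1 mixtures with heterodimer overrides
  reproducing the observed asymmetric stimulations
  ($\Delta_{asymm}$ +0.7 and +0.35), inhibited background wells, four
  replicates, 5 μM dimer, 0.6 mM NADH. The absolute WT turnover is set to
  0.5 μM ATP·min⁻¹·μM⁻¹, a typical basal rate for this chaperone class;
  Δ statistics are invariant to that absolute scale.
* `simulateTrajectory()`: multivariate-Gaussian displacements with a
  prescribed within/between-region block correlation (non-positive-definite
  requests are projected to the nearest PD matrix, with the distance
  logged in the truth record), mean positions on a coarse helix so
  superposition is never degenerate, optional rigid-body overlay.
* `simulateBuildup()`: shared-rate two-state exponential build-up.

What passing tests on these data do **not** show: real dispersion data can
violate the two-site fast-exchange assumption; real spectra have phase and
baseline distortions beyond a linear term; real plates show pipetting
covariance and coupled-enzyme lag, not iid noise; and real MD displacement
fields are neither Gaussian nor stationary. The generators validate the
estimators, not the physics.

# Problem sizes and reproducibility

The simulation studies shipped with the package use deliberately moderate
sizes — 100-profile recovery ensembles, 500 Monte Carlo draws, 1000-profile
null calibrations, 80-frame trajectory windows, 4096-point spectra — chosen
so the second moments they estimate are stable while a full run of the test
suite and the reproduction script stays in the minutes range.
`scripts/acceptance.R --seed <s> --out <path>` re-runs every headline
computation from scratch; all randomness flows from the single seed, and
outputs carry no timestamps, so a rerun with the same seed is
byte-identical.

# Known limitations

* The fast-exchange model cannot separate $p_B$ from $\Delta\omega$; only
  the product $R_{ex}$ is identifiable from dispersion alone.
* The 11-point single-field design partially aliases a large-$k_{ex}$
  branch; the multi-start handles it, but single-start refits of noisy
  replicates can land there (why the Monte Carlo uses the full multi-start).
* The build-up model is a documented single-exponential simplification of
  multi-step nucleotide binding kinetics.
* Δ-matrix deconvolution assumes the 1:2:1 dimer distribution has fully
  equilibrated before the assay.
* Correlations that project onto rigid-body modes are attenuated by
  superposition; region totals from differently superposed trajectories
  are comparable only under a common fitting convention.
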