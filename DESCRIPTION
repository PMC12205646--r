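Package: hsp90dyn
Title: Clamp-Cycle Dynamics of the Hsp90 Chaperone from NMR, ATPase, and
    Trajectory Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of the Hsp90 molecular clamp cycle.
    Fits 19F CPMG relaxation dispersion profiles to the two-state
    fast-exchange (Luz-Meiboom) model with Monte Carlo parameter errors
    and flat-versus-exchange model selection; extracts T2 values, peak
    areas, and exchange-averaged state populations from 1-D 19F spectra
    and fits slow conformational build-up time courses; converts
    NADH-coupled plate-reader progress curves into background-subtracted,
    WT-normalized ATPase activities, deconvolves 1:2:1 homodimer/
    heterodimer mixtures into pure heterodimer activity, and assembles
    the symmetric/asymmetric activity-modulation (Delta) matrix; computes
    dynamical cross-correlation matrices with Kabsch superposition and
    region-restricted total-correlation sums from molecular dynamics
    trajectory windows. Synthetic-data generators with recorded seeds and
    machine-readable ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
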