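Package: fretdyn
Title: Single-Molecule FRET and FRET-FCCS Analysis of Two-State
    Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying two-state open/close conformational
    dynamics of proteins from single-molecule fluorescence data.
    Implements corrected single-molecule FRET efficiency and
    Foerster-distance distributions with two-Gaussian decomposition and
    per-trajectory state classification, multi-tau correlation of
    time-tagged photon streams, closed-form FCS/FCCS correlation models
    with separate per-curve and global shared-parameter fitting
    including an intramolecular-dynamics time constant, and conversion
    between two-state rate constants, equilibrium populations and the
    relaxation time.  Includes seeded simulators for confocal photon
    streams (Brownian diffusion through a 3D Gaussian focus with
    two-state switching, triplet blinking, crosstalk and background)
    and for binned TIRF trajectories with photobleaching, so the whole
    pipeline is testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
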