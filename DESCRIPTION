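Package: teltrace
Title: Single-Molecule Magnetic-Tweezers Analysis of Telomere Mechanics
    and TRF1 Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule magnetic-tweezers
    experiments on telomeric DNA: worm-like-chain conversions between
    extension and base pairs, telomere-length measurement from force-ramp
    traces, step fitting of rupture and strand-separation traces, two-state
    hidden Markov analysis of fork-hopping traces with Boltzmann
    energetics, and the supporting kinetic fits (Bell-Evans, exponential
    dwell, Hill binding, Gaussian mixtures, partial correlations). A
    synthetic trace generator emulates the instrument assays (force ramp,
    force jump, hairpin strand separation, constant-force hopping) so that
    every analysis stage can be exercised and validated against known
    ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    minpack.lm,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
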