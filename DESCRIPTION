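Package: turingbranch
Title: Turing Instability Analysis of a Lung Branching-Morphogenesis Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a four-variable reaction-diffusion model of lung
    branching morphogenesis (Gierer-Meinhardt activator-inhibitor kinetics
    coupled to a consumable substrate and an irreversible cell-differentiation
    state) and analyses the Turing mechanism underlying its branching
    patterns. Provides the decoupled activator-inhibitor subsystem with
    frozen substrate and differentiation levels, its positive-equilibrium
    solver, linear stability analysis (dispersion relations, critical
    wavenumbers and wavelengths, Turing-condition scans over the
    substrate-differentiation parameter plane), explicit finite-difference
    simulators for both models, extraction of cell differentiation
    trajectories, and pattern quantification (spot counting, pattern
    classification, gradient statistics, radial power spectra, and
    tip-bifurcation versus side-branching event classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
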