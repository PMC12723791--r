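Package: gatednet
Title: Self-Adaptively Gated Associative Memory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and theory toolkit for two-layer associative memory
    networks in which a neuromodulator-like auxiliary layer multiplicatively
    gates the integration time-constants of an Amari-Hopfield neuronal layer.
    Provides compiled many-body Euler integrators with low-rank Hebbian drive,
    retrieval observables (Mattis overlaps, frozen/active sub-population
    decompositions), phase-diagram and storage-capacity sweeps, a
    self-consistent dynamical mean-field solver for the single-site process
    (two-time correlation and response functions, colored Gaussian noise,
    resummed memory kernel), time-asymptotic fixed-point equations for
    steady-state overlap bands, and two-pattern flow-map experiments that
    expose the continuous multistability induced by gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
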