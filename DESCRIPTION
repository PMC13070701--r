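Package: cestfit
Title: Two-State Chemical Exchange Analysis of CEST NMR Z-Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and global fitting of chemical exchange saturation
    transfer (CEST) NMR Z-spectra for two-state exchange. Provides three
    forward kernels (full 7x7 Bloch-McConnell propagation by matrix
    exponentiation, a fast analytical kernel built on the exact rotating-frame
    relaxation treatment of the two-site exchange generator, and a single-spin
    no-exchange control), Gaussian correction for RF (B1) field inhomogeneity,
    joint bound-constrained least-squares fitting of profiles acquired at two
    or more RF field strengths to extract exchange rates, minor-state
    populations, chemical-shift differences and relaxation rates, Monte-Carlo
    error estimation, plain-text profile and configuration I/O, and a
    reproducible synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
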