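Package: nmsse
Title: Non-Markovian Stochastic Schrodinger Equation Simulator for
    Donor-Acceptor Electron Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-level simulator of donor-to-acceptor electron
    transfer in a two-level receptor dimer coupled to a discrete
    vibrational mode and embedded in a structured environment. Implements
    the perturbative time-local non-Markovian stochastic Schrodinger
    equation (NMSSE) driven either by colored complex Gaussian noise with
    a prescribed finite-temperature bath kernel (harmonic bath) or by a
    compensated filtered compound-Poisson shot-noise process with unitary
    kick events (anharmonic, non-Gaussian bath). Provides structured
    spectral densities, memory coefficients, variance-matched bath
    comparison, ensemble observables (populations, coherence, vibrational
    occupation), dimensionless regime diagnostics, and two-dimensional
    transfer-probability scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
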