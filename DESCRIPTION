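Package: switchsir
Title: Regime-Switching Stochastic SIR Models with Ratio-Dependent Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a two-compartment SIR epidemic model whose transmission
    is ratio-dependent (saturating in the infected-to-susceptible ratio) and
    whose parameters switch between environmental regimes driven by a
    continuous-time Markov chain, with multiplicative white noise on the
    transmission coefficient entering susceptible and infected compartments
    with opposite signs (degenerate diffusion). Provides closed-form threshold
    quantities (the per-regime basic reproduction number, the stochastic
    reproduction number weighted by the chain's stationary distribution, and
    an extinction index), a persistence/extinction classifier, exact
    continuous-time Markov chain path simulation, a fixed-step fourth-order
    integrator for the deterministic skeleton, a strong-order-one Milstein
    integrator for the switching diffusion, ensemble summaries with
    regime-conditional histograms, coupled-refinement strong-order
    diagnostics, and a JSON configuration interface with a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
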