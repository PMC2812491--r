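Package: enkin
Title: Ensemble Kinetic Modeling of Mass-Action Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds mass-action ordinary differential equation models of
    protein signaling networks from a plain-text reaction format, estimates
    an ensemble of rate constants from immunoblot-style training data that
    are accurate only up to a multiplicative constant (Metropolis random
    walk in log-parameter space with autocorrelation thinning), and
    interrogates the fitted ensemble with forward kinetic sensitivity
    analysis (overall state sensitivity coefficients and rank-shift tests
    between cell-line clones), in-silico knock-in/knock-down/knock-out
    robustness coefficients, and dual-knockout synergy coefficients.
    Ships a reduced synthetic receptor/MAPK/Akt-translation signaling
    network with androgen-dependence-like clone variants so the whole
    workflow runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
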