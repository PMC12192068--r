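Package: siirrwave
Title: Two-Strain SIIRR Epidemic Model of Popularity Waves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of a five-compartment two-strain
    epidemic model (SIIRR: susceptible, two mutually exclusive infected
    classes, two recovered classes with permanent cross-protective
    immunity) used as a mathematical theory of coexisting waves of
    positive and negative popularity. Provides a deterministic ODE
    simulator with conservation and monotonicity guarantees, fixed-point
    enumeration with closed-form and numerical Jacobian eigenvalue
    analysis, the closed-form Riccati solution chain for the
    near-threshold single-dominant-strain regime (tanh cumulative curves,
    sech-squared infection bells) with validity-regime diagnostics, a
    registry of reference scenarios, one-parameter sweeps, and detectors
    for the named popularity-wave effects (suppression, forgetting,
    window of dominance, single peak, short-term win-long-term loss,
    peak shift, faster increase-faster decrease).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
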