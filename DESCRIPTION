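Package: oscrobust
Title: Robustness of Period and Amplitude in Limit-Cycle Oscillator Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the robustness of the period and amplitude of
    limit-cycle oscillations in ODE models of cellular processes such as
    circadian clocks and calcium signalling. Parameter sets are obtained by
    bottom-up Monte-Carlo sampling of steady-state concentrations, balanced
    reaction flows and nonlinear kinetic parameters, with rate coefficients
    back-solved from the steady-state condition. Sampled states are screened
    for linear instability of the steady state, integrated with a dual
    (non-stiff/stiff) solver policy, checked for regular oscillations, and
    confirmed at tightened tolerances. Scalar period and amplitude
    sensitivities are computed from one-at-a-time relative parameter
    perturbations and summarised across thousands of accepted parameter
    sets. Ships the Goodwin-type negative-feedback and substrate-depletion
    positive-feedback chain-model families (mass-action or Michaelis-Menten
    kinetics, mass conversion or regulated production variants) and two
    published oscillator models as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
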