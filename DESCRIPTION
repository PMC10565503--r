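Package: kpdbmd
Title: Kinetic-Pharmacodynamic Modelling of Bone Mineral Density Under
    Zoledronic Acid Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dose-driven (kinetic-pharmacodynamic, K-PD) indirect-response
    modelling of lumbar-spine bone mineral density under intravenous
    zoledronic acid. Implements the structural model (virtual dose
    compartment, Emax stimulation of bone formation, exponential
    tolerance), a nonlinear mixed-effects estimation layer with a Laplace
    approximation to the marginal likelihood, synthetic trial-arm data
    generation, model diagnostics (goodness-of-fit residuals, visual
    predictive checks, nonparametric bootstrap), pooled exposure-response
    analysis of acute-phase-reaction incidence, and stochastic simulation
    of candidate dosing regimens against a percent-change-from-baseline
    efficacy rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    rlang,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
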