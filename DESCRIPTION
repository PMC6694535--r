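Package: cvdsim
Title: Population-Level System-Dynamics Simulation of Cardiovascular Disease
    Outcomes Under Risk-Factor Management Policies
Version: 0.1.0
Authors@R:
    person("cvdsim", "developers", email = "cvdsim@example.org", role = c("aut", "cre"))
Description: A deterministic stock-and-flow (system dynamics) simulator of
    cardiovascular disease (CVD) events, CVD deaths and the post-CVD population
    in an ageing national population. Three risk-factor compartment sub-models
    (diabetes, hypertension, smoking) with managed/unmanaged treatment states
    feed an eight-risk-group Framingham-style logistic CVD event engine with
    treatment-adjusted event probabilities. Includes intercept calibration to an
    expert distribution of events by risk group, transition-rate fitting to
    prevalence and event time series, policy scenario experiments, Monte-Carlo
    parameter sensitivity analysis, and a synthetic-demography generator that
    stands in for national statistical and disease-registry inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
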