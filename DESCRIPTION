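Package: lungpk
Title: Semi-Mechanistic Regional Lung Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-mechanistic pharmacokinetic modelling of regional drug
    retention in the lung after intravenous infusion. Simulates plasma and
    virtual tissue compartments (trachea, bronchi, alveolar parenchyma)
    driven by perfusion-limited distribution with tissue-to-plasma partition
    coefficients, estimates tissue affinities and localized pulmonary blood
    flows by two-stage nonlinear regression with flows shared across drugs,
    derives pulmonary absorption half-lives with allometric scaling to
    human, quantifies time-dependent bias of plasma-derived EC50 estimates
    under an Emax effect model, and evaluates tissue sampling designs by
    stochastic simulation and estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
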