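Package: anesdepth
Title: Pharmacokinetic-Pharmacodynamic Modelling of Anesthesia Depth with
    Particle Swarm Identification and Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the depth of anesthesia as measured by the
    bispectral index (BIS). Simulates drug disposition with a covariate
    parameterized three-compartment pharmacokinetic model driven by bolus
    plus infusion dosing, links plasma to effect-site concentration with a
    first-order equilibration, and maps effect-site concentration to BIS
    through a sigmoid Emax (Hill) pharmacodynamic model. Per-patient Hill
    parameters are identified from observed BIS traces by particle swarm
    optimization, and BIS can alternatively be regressed from EEG-derived
    spectral features with a from-scratch gradient-boosted regression tree
    learner. Includes goodness-of-fit metrics (R squared, RMSE, MAPE), a
    virtual-patient cohort generator for parameter-recovery studies, and a
    pipeline that produces per-patient fit reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
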