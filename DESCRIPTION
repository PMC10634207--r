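Package: bpcutoff
Title: Population Pharmacokinetics and PK/PD Cutoff Determination for
    Benzylpenicillin in Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive pharmacokinetic/pharmacodynamic (PK/PD) cutoff
    values for benzylpenicillin in horses, supporting clinical-breakpoint
    setting for antimicrobial susceptibility testing. Implements closed-form
    simulation of mammillary compartmental models with the intramuscular
    absorption schemes used for equine benzylpenicillin formulations
    (first-order, sequential dual rate with lag, parallel dual, per-site
    sequential), population sampling with log-normal between-subject
    variability and categorical covariates on clearance, free-concentration
    PK/PD indices (fAUC/MIC and fT>MIC), Monte Carlo probability of target
    attainment and cutoff selection, non-compartmental analysis, a desk-scale
    nonlinear mixed-effects estimator with a Laplace-type marginal likelihood,
    visual predictive checks, and synthetic multi-country study generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
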