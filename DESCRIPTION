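Package: voripopk
Title: Population Pharmacokinetics of Voriconazole in Critically Ill
    Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-compartment population pharmacokinetic modelling of
    voriconazole in intensive-care patients: closed-form kinetics with
    first-order oral absorption and zero-order infusion, a covariate model
    on clearance (quick C-reactive protein, continuous renal replacement
    therapy, creatinine clearance, platelet count, prothrombin time),
    FOCE-style nonlinear mixed-effects estimation with empirical-Bayes
    random effects, stepwise covariate selection, nonparametric bootstrap,
    prediction-corrected visual predictive checks, conditional weighted
    residuals, and Monte Carlo probability-of-target-attainment simulation
    against the free-drug AUC to MIC ratio target. Includes a synthetic
    event-dataset generator emulating a mixed sparse-trough and intensive
    sampling therapeutic drug monitoring design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
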