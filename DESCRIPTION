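Package: clubmsm
Title: Marginal Structural Models for Adherence-Club Cohorts on ART
Version: 0.1.0
Authors@R:
    person("Alex", "Veld", email = "alex.veld@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the intention-to-treat effect of
    adherence-club participation on retention in HIV care and virologic
    rebound from longitudinal clinic register data. Implements discrete-time
    person-month cohort construction with last-observation-carried-forward
    covariates, stabilized inverse-probability-of-treatment and censoring
    weights, weighted pooled logistic regression with restricted cubic
    spline time and patient-clustered sandwich variance, exact Poisson rate
    descriptives, and a synthetic cohort generator with a counterfactual
    oracle for validating the whole pipeline against a known marginal
    hazard ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
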