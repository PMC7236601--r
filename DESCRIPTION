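Package: thyropd
Title: Pharmacodynamic Modelling of Carbimazole Response in Graves' Hyperthyroidism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the pharmacodynamic response of thyroid
    hormones to carbimazole in Graves' disease. Implements a recursive daily
    thyroid-hormone response model (forward simulation, parameter fitting with
    an optional dose exponent, weight adjustment, RMSE assessment, and inverse
    dose recommendation), baseline hormone/antibody regressions, percentage
    fall-per-day dose-response lines by treatment phase, relapse risk
    stratification with an additive relapse rate score, and a calibrated
    synthetic longitudinal cohort generator for exercising every stage without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
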