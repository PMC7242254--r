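Package: phscreen
Title: Screening Analytics for Echocardiography-Detected Pulmonary
    Hypertension in Interstitial Lung Disease
Version: 0.1.0
Authors@R:
    person("phscreen", "developers", email = "phscreen@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving and evaluating non-invasive predictors of
    pulmonary hypertension (PH) in newly diagnosed interstitial lung
    disease.  Provides derived pulmonary-function indices (notably the
    TLC/DLCO ratio), the 2009 ESC/ERS echocardiographic PH-probability
    classifier, empirical ROC curves with DeLong confidence intervals and
    Youden-optimal cutpoints, univariate logistic regression and 2x2 odds
    ratios, a composite 10-point PH-prediction score, and a synthetic
    two-group cohort generator that emulates the published group-level
    means and standard deviations so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
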