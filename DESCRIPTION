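Package: oculobox
Title: Binocular Eye-Tracking Disconjugacy Biomarkers for Concussion Screening
Version: 0.1.0
Authors@R:
    person("Oculobox", "Developers", email = "oculobox@example.org",
           role = c("aut", "cre"))
Description: Simulation, preprocessing, and statistical analysis of binocular
    pupil-position recordings acquired while a subject tracks an aperture
    circling the edges of a viewing monitor. Provides a synthetic cohort
    generator with controllable gaze disconjugacy, blink-aware cleaning and
    trial-triggered ("box trajectory") averaging, a registry of 89 named
    oculomotor metrics, univariate biomarker screening with Bonferroni
    multiplicity control and covariate exclusion, classifier building by
    best-subset logistic regression, L1-penalized logistic regression and a
    bagged tree ensemble, repeated stratified cross-validation, and
    ROC/confusion-matrix evaluation against external validation cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
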