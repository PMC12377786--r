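Package: gdmnoise
Title: Synthetic EHR Cohorts and Label-Noise Experiments for Gestational
    Diabetes Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how outcome-label errors in electronic
    health records distort clinical risk prediction models, using
    gestational diabetes mellitus (GDM) screening as the running example.
    Generates synthetic antenatal cohorts with a latent logistic risk
    model, corrupts outcome labels with a class-conditional
    noise-at-random process emulating EHR/registry discordance,
    quantifies label agreement (confusion composition, rates, Cohen's
    kappa, per-year drift), and measures how train-set versus test-set
    label noise moves logistic-regression discrimination (ROC AUC,
    average precision) and calibration (slope, intercept), including a
    closed-form mixture oracle for AUC under test-label noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
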