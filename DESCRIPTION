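Package: abtp
Title: Abnormal Body Temperature Probability Models for Dairy Cattle
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sigmoid dose-response models for the probability of abnormal body
    temperature (ABTP) in dairy cattle under heat stress, with the
    temperature-humidity index (THI) as the quantitative risk factor.  Provides
    the LKB (probit), logistic, log-logistic (Schultheiss) and Poisson tolerance
    curve families fitted by maximum likelihood, TT50/TT20 quantile inversion,
    an LKB effective-index model coupling THI and body temperature through a
    power law, LASSO-based risk-factor ranking, a synthetic herd generator
    calibrated to published summary statistics, triage banding of body
    temperatures, and a model-comparison battery (AUC with DeLong confidence
    intervals, accuracy, AIC and delta-AIC, Brier score, Hosmer-Lemeshow test,
    calibration curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
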