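Package: vmatqa
Title: Aperture Complexity Metrics and QA Outcome Prediction for VMAT Plans
Version: 0.1.0
Authors@R:
    person("VMAT QA", "Maintainers", email = "vmatqa@example.org", role = c("aut", "cre"))
Description: Quantifies the deliverability of volumetric modulated arc
    therapy (VMAT) treatment beams from their control-point sequences.
    Reads DICOM-RT Plan objects (and a plain-text JSON plan dialect),
    derives per-control-point aperture geometry on a multi-leaf
    collimator, and computes 27 beam complexity metrics including the
    modulation complexity score family, edge and small-aperture scores,
    a fluence modulation index, and the aperture-perimeter-variability
    based LAAM score. Links metrics to measured gamma passing rates via
    Spearman correlation and ROC threshold analysis, and predicts
    passing rates with built-in random forest and gradient boosting
    regressors. Includes a deterministic synthetic plan/cohort generator
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
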