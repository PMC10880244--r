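Package: icibench
Title: Predictive-Versus-Prognostic Benchmarking of Immune Checkpoint
    Inhibitor Response Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluation framework for predictive biomarker models in
    two-arm immunotherapy trials. Scores patients with rule-based and
    signature-based models of immune checkpoint inhibitor benefit
    (TMB/PD-L1 decision rules, single-sample gene-signature scores,
    linear covariate models), computes per-arm basal metrics (Harrell's
    concordance index, ROC-AUC) and the difference in squared scaled
    basal metrics (DSS) that separates treatment-specific predictive
    signal from arm-agnostic prognostic signal, ranks models by
    paired-bootstrap Bayes factors with nivolumab-arm tie-breaking, and
    ships a synthetic two-arm trial generator with configurable
    prognostic and predictive biomarker effects, latent-factor
    expression, censoring, and missingness so the whole pipeline is
    testable without restricted clinical-trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
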