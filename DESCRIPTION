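Package: metevroc
Title: Biomarker Discovery and Cross-Validated ROC Evaluation for
    Fecal Microbial EV Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for case/control metabolomics biomarker
    discovery, built around the analysis design used for fecal
    microbial extracellular-vesicle (EV) metabolite profiles in
    colorectal cancer screening. Implements sample-median normalization
    and Pareto scaling, per-metabolite differential screening (Welch
    t-test with Benjamini-Hochberg false-discovery-rate control, raw-scale
    fold changes, volcano classification), empirical univariate ROC
    analysis with stratified bootstrap confidence intervals and optimal
    cutoffs, a dual-criterion biomarker filter (adjusted p-value and AUC),
    and balanced Monte-Carlo cross-validated multivariate ROC evaluation
    with linear SVM, PLS-DA (NIPALS, implemented here) and random-forest
    classifiers. A calibrated log-normal cohort simulator reproduces the
    statistical structure of the target study design so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
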