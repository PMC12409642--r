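Package: gendrad
Title: Gender-Stratified Radiomic Modelling of Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gender-stratified machine-learning framework for predicting
    three-year disease progression from CT radiomic feature tables in
    resectable colorectal liver metastases. Provides stability-based feature
    selection by rank-sum resampling, detection of confounding patients via
    repeated multi-classifier subsampling, an AUC-weighted soft-voting
    ensemble of five classifiers with Youden-index thresholding, repeated
    stratified 10-fold cross-validated evaluation with mean and 95%
    confidence-interval summaries, Hanley-McNeil AUC comparison between
    models, clinical-covariate comparability testing, and a synthetic cohort
    generator that emulates the statistical structure such analyses assume
    (gender-disjoint discriminative features, correlated feature blocks,
    label-noise confounders).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
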