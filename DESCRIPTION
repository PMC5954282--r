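Package: uipclassify
Title: Development Workflow for a Genomic UIP Classifier on Transbronchial
    Biopsy RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and validating a clinical RNA-seq
    classifier of usual interstitial pneumonia (UIP) from multiple
    transbronchial biopsies per patient. Implements frozen median-of-ratios
    normalization with a closed-form variance-stabilizing transformation,
    batch-robust gene filtering from variance components fitted on sentinel
    replicates, in-silico within-patient sample mixing with technical-noise
    replication, patient-stratified (leave-one-patient-out) nested
    cross-validation of penalized logistic classifiers, prospective
    decision-boundary selection under sensitivity and specificity
    constraints, and score-level batch-effect monitoring. Includes a
    synthetic cohort generator that emulates the hierarchical structure of
    a multi-sample-per-patient biopsy study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    DESeq2,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
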