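Package: oncodual
Title: Cancer Hotspot Overlap as Calibrated Evidence for Germline Variant
    Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts recurrent somatic cancer-hotspot mutation data into
    calibrated evidence for the pathogenicity of germline missense variants.
    Provides readers for hotspot and ClinVar-style germline variant tables,
    overlap annotation at the nucleotide or amino-acid-change level,
    odds-ratio and positive-likelihood-ratio contingency analysis with
    Woolf confidence intervals, mapping of likelihood ratios onto the
    exponential ACMG/AMP evidence-strength point scale, an ACMG/AMP
    combining-rule engine with a VUS-upgrade simulation, tumor-sample-count
    ROC filtering of COSMIC-style mutation tables, weighted logistic
    regression and random forest pathogenicity models with a REVEL-based
    prior-weighting scheme, precision-recall and ROC evaluation with k-fold
    cross-validation, and a synthetic cohort generator with controllable
    overlap enrichment for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
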