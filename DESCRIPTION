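Package: famhx
Title: Family History of Psychiatric Disorder: Extraction from Admission
    Notes and Impact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies family-history-of-psychiatric-disorder events in
    free-text psychiatric admission notes and quantifies their association
    with the first diagnosis at admission.  Provides a seeded synthetic
    admission-note generator with known ground truth; a rule-based
    annotator (dictionary segmentation, family-history section location,
    negation handling, kinship-degree extraction); a multi-label neural
    text classifier (token embeddings, optional small contextual encoder,
    multi-width convolutions with ReLU and max-over-time pooling, sigmoid
    output) with grid search and a rule-hybrid post-filter; patient-level
    bitwise-OR label merging; micro/macro precision-recall-F1, ROC/AUC and
    multi-run evaluation; and a chi-squared plus stepwise adjusted
    logistic-regression association stage reporting odds ratios with 95
    percent confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
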