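Package: raschDRG
Title: Detecting DRG Up-Coding in Hospital Claims with a Continuous-Response Rasch Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Norm-referenced detection of probable reimbursement deductions
    (up-coding) in diagnosis-related-group (DRG) hospital claims. Fee items are
    min-max normalised to the unit interval and modelled with a one-parameter
    Rasch model for continuous responses; item difficulties are calibrated per
    DRG on a norm group of clean claims by joint maximum likelihood, new
    discharge cases are scored by standardized residual Z-scores per fee item
    (estimating ability from observed items only), and items with Z > 2 are
    flagged as probable deductions. Includes accuracy-table, chi-square and
    ROC-AUC evaluation against audit labels, a synthetic claims generator with
    known truth, and a bubble-chart dashboard payload exporter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
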