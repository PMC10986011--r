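Package: haplomet
Title: Read-Level Methylation Haplotype Metrics and Blood-Based Diagnostic
    Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for read-level bisulfite methylation haplotype analysis:
    parsing and writing mHap-style haplotype files, calling methylation
    haplotype blocks (MHBs) from pairwise methylation linkage
    disequilibrium, computing six haplotype-level block measurements
    (AMF, MHL, UMHL, MHL3, UMHL3, PDR), screening and selecting
    differential markers (coverage filtering, Mann-Whitney screening,
    KNN imputation, recursive feature elimination with cross-validation),
    training a random-forest diagnostic classifier with a Youden-derived
    decision threshold, and producing stratified diagnostic evaluations
    against an ultrasonography comparator. Includes a fully seeded
    synthetic-cohort generator with planted ground truth so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
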