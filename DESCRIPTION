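Package: markertree
Title: Decision-Tree Biomarker Discovery for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies small, interpretable biomarker panels from two-class
    (tumor versus normal) log2 expression matrices. Provides a
    differential-expression prefilter (two-sample t-tests with
    Benjamini-Hochberg correction and an overexpressed-in-tumor rule),
    C4.5-style decision-tree induction on continuous features with
    error-based confidence pruning and if-then rule extraction,
    leave-one-out and stratified k-fold cross-validation, and a greedy
    sequential forward feature-selection wrapper that maximizes
    cross-validated tree accuracy. Also includes spot- and array-level
    quality-control utilities for spotted microarrays and a synthetic
    expression-data generator with planted single and complementary-pair
    markers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
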