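Package: appsig
Title: Bootstrap Discovery of Gene-Expression Biomarker Signatures for
    Pediatric Appendicitis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and out-of-bag validation of small gene-expression
    biomarker signatures that separate phlegmonous (uncomplicated) from
    gangrenous (complicated) pediatric appendicitis. Implements the full
    analysis chain for a two-class intensity matrix: quantile normalization
    and log2 transformation, per-gene Welch unequal-variance t-tests with
    log2 fold changes, bootstrap resampling that alternates discovery and
    validation sets, nested top-k candidate signatures ranked by the
    discovery-set Welch statistic, ridge-penalized logistic regression
    fitted by iteratively reweighted least squares, and threshold-swept
    ROC aggregation with bootstrap standard errors and confidence limits.
    A seeded synthetic-data generator emulates the study design (13 vs 16
    samples, tens of thousands of genes, a handful of informative genes)
    so every stage is testable without the deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
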