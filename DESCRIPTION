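Package: igsig
Title: Integral Genomic Signature Modeling of Pharmacogenomic Drug Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transparent, redundancy-aware prediction of therapeutic response
    from multi-omics data. Converts gene expression and somatic mutation
    profiles into overlapping multi-level binary genomic features (GMT-backed),
    weights each feature's association with drug sensitivity or resistance by a
    weighted Kolmogorov-Smirnov enrichment statistic calibrated by permutation,
    and scores subjects by summing feature weights penalized for redundancy
    estimated from feature co-occurrence (Otsuka-Ochiai similarity) in an
    unlabeled reference cohort. Includes waterfall-based drug-response
    labelling, cross-dataset model application and evaluation, and a synthetic
    pharmacogenomic cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    limma,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
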