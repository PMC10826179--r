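Package: mirpanel
Title: FFPE miRNA qPCR Panel Analysis: Normalization, Differential
    Expression, Nested-CV Classification and Target-Gene Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of focused miRNA RT-qPCR panels profiled from
    formalin-fixed paraffin-embedded (FFPE) lymph node tissue. Implements
    spike-in and global-mean Ct normalization with low-detection filtering,
    per-miRNA differential expression (Student's t with Benjamini-Hochberg
    FDR), nested cross-validated elastic-net logistic regression and random
    forest classifiers with permutation feature importance, and miRNA
    target-gene set enrichment tested against a miRNA-resampling permutation
    null. A synthetic cohort generator with planted class effects, technical
    offsets and detection dropout makes every stage testable without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
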