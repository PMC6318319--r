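Package: scmmsig
Title: Single-Cell Expression Signatures of Multiple Myeloma Progression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving progression gene signatures from
    single-cell RNA-seq of plasma cells: quality-control filtering of cells
    by sequencing metrics, CDS-restricted TPM normalization,
    coefficient-of-variation selection of variable genes, unsupervised
    hierarchical clustering of cells (1 - Pearson correlation distance,
    Ward.D2 linkage) into ordered risk groups, group-wise ANOVA and
    fold-change screening yielding a monotone progression signature,
    hypergeometric gene-set over-representation, and survival stratification
    of an external expression cohort by K-means dichotomization with
    Kaplan-Meier, log-rank and hazard-ratio comparisons. Includes a
    negative-binomial synthetic-data generator with planted group structure
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    survival,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
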