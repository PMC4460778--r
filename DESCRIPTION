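Package: transcoex
Title: Transnosological Coexpression Analysis of Multi-Batch Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates multi-batch gene expression matrices (quantile
    normalization, probe collapsing, empirical-Bayes batch adjustment),
    discovers correlation-based biclusters under an average Pearson
    correlation threshold, refines them into disease-class-complete gene
    sets, tests each set for significant gain or loss of coexpression
    relative to controls with a random-gene-group permutation null and
    Benjamini-Hochberg correction, and summarizes how gene sets are shared
    across disease combinations, including hypergeometric category
    enrichment.  Ships a synthetic multi-batch cohort generator with
    planted, class-restricted coexpression modules so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
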