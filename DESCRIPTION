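Package: gemscan
Title: Fast Genome-Scale Linear Models for Methylation, Genotype and
    Environment Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fast, memory-bounded engine for epigenome-wide association
    scans. Implements three genome-scale linear models -- methylation
    versus environment (Emodel), methylation versus genotype, i.e. methQTL
    mapping (Gmodel), and methylation versus genotype-by-environment
    interaction (GxEmodel) -- computed by covariate projection and
    standardized inner products in matrix blocks, with mean-value
    imputation of missing cells, Benjamini-Hochberg false discovery rate
    control, cis/trans/disrupting pair classification, QQ and
    genotype-segregation diagnostics, a synthetic-data generator with
    planted effects, and a naive per-pair least-squares oracle used to
    verify the fast path.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
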