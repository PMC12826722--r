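Package: gaclock
Title: Epigenetic Gestational Age Analysis: EWAS, Regional Methylation, and
    Penalized Clock Models for Cord-Blood Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for cord-blood DNA methylation analysis of gestational
    age (GA): probe quality control and quantile normalization, latent
    confounder estimation, single-CpG epigenome-wide association (EWAS) with
    Benjamini-Hochberg false discovery control and genomic-inflation
    diagnostics, region detection by correlated p-value combination
    (Stouffer-Liptak with autocorrelation weights and Sidak search-space
    correction), nearest-gene functional annotation with hypergeometric and
    Fisher-exact enrichment, an elastic-net epigenetic gestational age (EGA)
    clock with cross-validated age-acceleration (EGAA) estimates, and
    single/multi-exposure linear models with AIC backward selection. A
    synthetic-cohort generator provides a ground-truth test bed at array
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    limma,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
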