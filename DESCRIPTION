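Package: sexdimorph
Title: Sex-Informed Differential Expression and X-Chromosome Dosage Analysis
    for Brain Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for sex-informed analysis of bulk RNA-seq
    count data: TPM and TMM/log-CPM normalization with voom-style precision
    weights, covariate screening and hidden-factor estimation, empirical-Bayes
    moderated differential expression under sex, sex-by-region,
    sex-by-diagnosis and diagnosis-within-sex designs, relative X-chromosome
    expression (RXE) dosage statistics, X-inactivation (XCI) status
    enrichment, a stringent sex-specific differential expression filter, a
    male-subsampling permutation null, and cross-dataset replication
    statistics (pi1, effect-size concordance, overlap enrichment). Ships a
    negative-binomial synthetic-data generator that emulates the statistical
    structure of a multi-region case/control brain cohort so the whole
    pipeline is testable without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    limma,
    Matrix,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
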