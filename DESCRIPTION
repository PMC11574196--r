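Package: mitoseg
Title: Single-Cell Dynamics of Mitochondrial DNA Heteroplasmy Segregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how two mitochondrial DNA (mtDNA) variants segregate
    in proliferating budding-yeast populations. Provides a stochastic
    array-based simulator of mtDNA partitioning with relaxed (Polya-urn)
    replication, fission-fusion shuffling and asymmetric mother-daughter
    division; quantification of per-cell fluorescence into heteroplasmy
    (h) values; Gaussian-mixture thresholding and cell classification;
    least-squares grid fitting of the simulator to empirical homoplasmy
    time courses; pedigree-based mother-progeny correlation analysis;
    fluorescence-decay and nucleoid-transfer kinetics estimators; and a
    synthetic-data generator that emulates time-lapse per-cell tracking
    tables so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    withr,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
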