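Package: orthoenrich
Title: Cross-Species Enrichment of GWAS Variants in Ortholog Regions of
    Mammary Cancer Susceptibility Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether human genome-wide association study
    (GWAS) nominated breast cancer risk SNPs fall inside human orthologs of
    rat mammary cancer susceptibility loci more often than inside randomly
    drawn control regions of the rat genome. Provides genomic interval
    algebra and coverage accounting (total, overlapping and unique bases,
    genome fraction), a rat-to-human ortholog fragment table with the 1%
    fragment-retention rule, a seeded rejection sampler for random control
    regions with locus-ortholog and centromere exclusion, SNP catalog
    deduplication and count-once region assignment, observed-versus-expected
    chi-square and 2x2 logistic (Wald and likelihood-ratio) enrichment
    statistics with ratio normalisation, and a synthetic-data generator
    with a configurable enrichment multiplier for end-to-end calibration.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
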