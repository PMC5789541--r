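Package: microgwas
Title: Host Genetic Variation and Microbiome Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for associating host genetic
    variation with microbiome composition in cohorts profiled at multiple
    body sites. Provides genotype quality control, principal component
    analysis of population structure, robust (KING-style) kinship
    estimation with relatedness-degree classification, microbiome
    feature preparation (replicate averaging, prevalence filtering,
    log transformation), a permutation-null variance-explained framework
    linking genetic principal components to microbial features, rank-based
    pathway superclass enrichment, relatedness versus community-similarity
    comparisons, targeted genotype-taxon tests, and a covariate-adjusted
    genome-wide association scan with clumping and gene annotation.
    Includes a synthetic cohort generator (structured genotypes with
    pedigree pairs, zero-inflated compositional abundance profiles with
    planted effects) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
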