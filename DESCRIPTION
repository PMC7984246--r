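Package: gxediv
Title: Genotype-by-Environment Diversification Analysis for Experimentally
    Evolved Microbial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies diversification in experimentally evolved microbial
    populations from three data streams. Decomposes clone-by-substrate
    catabolic profiles (e.g. Biolog OD660 plates) into phenotypic, genotypic,
    environmental and genotype-by-environment variance components, the latter
    split into responsiveness and inconsistency. Computes odds-ratio relative
    fitness from blue/white competition colony counts with Holm-adjusted
    pairwise contrasts. Summarises pooled-sequencing variant-proportion tables
    into genetic distance, variant counts and expected-heterozygosity alpha
    diversity, and compares treatment groups with permutation-based
    multivariate ANOVA, beta-dispersion and non-metric multidimensional
    scaling. A seeded synthetic-data generator emulates specialist and
    generalist evolved populations so every stage of the pipeline is testable
    without external data.
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
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
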