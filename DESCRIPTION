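Package: pstfst
Title: Phenotypic and Neutral Genetic Divergence Among Wild Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing phenotypic divergence (P_ST) in quantitative
    traits with neutral genetic differentiation (Weir-Cockerham F_ST) across
    wild populations. Provides SNP genotype input and filtering, per-population
    genetic diversity indices (observed and expected heterozygosity, Nei gene
    diversity, polymorphism information content, nucleotide diversity,
    Tajima's D), pairwise multi-locus F_ST, one-way ANOVA variance components
    and P_ST with heritability sensitivity analysis and critical-c estimation,
    geographic and environmental distance matrices, Mantel and partial Mantel
    permutation tests, and a Balding-Nichols simulator for generating synthetic
    study designs with known ground truth. All user-facing functions return
    tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
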