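Package: neotrack
Title: Neo-Epitope Discovery and T Cell Receptor Clonotype Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering and validating
    neo-epitope-specific CD8+ T cells in low-mutational-load tumors:
    enumeration of mutant 9/10-mer peptides around somatic missense
    mutations, MHC class I binding-affinity filtering at 500 nM,
    ELISpot response calling by the mean-plus-3-SD rule, intracellular
    cytokine polyfunctionality decomposition, four-parameter logistic
    EC50 (functional avidity) estimation with bootstrap intervals,
    chromium-release specific lysis, TCR clonotype repertoire
    construction with out-of-frame and singleton filtering, and
    cross-compartment clonotype tracking against a detection limit.
    A seeded synthetic-cohort generator emulates the statistical
    structure of a small ovarian-cancer cohort so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
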