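Package: cardiohep
Title: Cardiomyocyte Morphometry, Collagen Quantification and Serum
    Analytics for Rodent NAFLD Cardiovascular-Risk Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy analysis pipeline for rodent studies linking
    nonalcoholic fatty liver disease to cardiovascular risk. Measures
    cardiomyocyte cross-sections from labeled histology images (area plus
    four shape descriptors), computes the cardiomyocyte irregularity index
    (CII), gates cells into size-by-shape morphometric classes against a
    control-derived reference band, and summarises per-animal population
    profiles. Quantifies picrosirius-red collagen as stained area fraction
    and intensity, computes atherogenic lipid ratios (Castelli risk
    indices, atherogenic coefficient), derives 2^-ddCt relative expression
    of circulating microRNAs against a spike-in normalizer, and runs the
    normality-gated group-comparison workflow (Shapiro-Wilk gate, ANOVA
    with Tukey HSD or Kruskal-Wallis with Dunn's test, compact letter
    display). Ships a seeded synthetic-data generator producing
    ground-truthed cell fields, collagen fields, serum panels and qPCR Ct
    tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
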