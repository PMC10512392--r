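Package: synergyscreen
Title: Chemogenomic Screening and Scoring of Antifungal Drug Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for yeast drug-combination screening: reduces
    plate-reader growth curves to inhibition ratios and average generation
    times, scores checkerboard dose matrices with the Bliss multiplicative
    epsilon (AvgS) plus Loewe, highest-single-agent and potentiation
    confirmatory models, calls negative drug-gene interactions from
    heterozygote fitness tables, predicts synergistic pairs from single-agent
    chemogenomic profiles, processes barcode-microarray HIP-HOP screens into
    robust Z-score fitness-defect profiles with combination-specific strain
    calling and sensitivity epsilon, and ranks gene-set enrichment of
    combination profiles. A synthetic-data module generates growth curves,
    five-screen barcode tables and prediction worlds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
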