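Package: cwevalkit
Title: Composite Treatment Scoring and Microbial Community Response for
    Constructed-Wetland Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates constructed-wetland microcosms treating antibiotic
    wastewater. Builds a factor-analysis-weighted composite treatment score
    from pollutant removal rates (KMO and Bartlett adequacy diagnostics,
    eigendecomposition with Kaiser retention, varimax rotation, explained-
    variance factor weights and within-factor normalized indicator weights),
    and quantifies the microbial community response with alpha-diversity
    indices (Chao1, Shannon, Gini-Simpson, Good's coverage), Bray-Curtis/
    UPGMA beta diversity, an LDA-effect-size style differential-genus
    procedure, and genus-pollutant correlation networks. Includes seeded
    synthetic-data generators for removal kinetics, overdispersed count
    communities and logistic microalgal growth, plus an OD680-to-biomass
    calibration, so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
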