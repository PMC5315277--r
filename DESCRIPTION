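Package: dustballast
Title: TEP Size Spectra and Lithogenic Ballast Budgets for Dust-Seeding
    Minicosm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dust-seeding minicosm experiments on
    abiotic organic-carbon export. Computes transparent exopolymer particle
    (TEP) number-size-distribution statistics (power-law spectral slope,
    abundance-weighted mean diameter, volume concentration) from per-size-class
    counts; converts sediment-trap elemental compositions into PIC/POC
    partitioning, POC stocks and fluxes, and aluminium-proxy lithogenic
    fluxes; fits the zero-intercept ballast regression of POC flux on
    lithogenic flux and applies it to event-scale and annual-scale dust
    deposition. A seeded synthetic-data generator emulates power-law TEP
    counts and dust/organic-matter trap mixtures so every stage is testable
    without raw microscopy or trap data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
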