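Package: camtrappair
Title: Paired Camera-Trap Encounter-Rate Analysis for Logging Concessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired camera-trap surveys of forest mammal
    communities, built around the design in which each certified logging
    concession is matched to a nearby non-certified concession. Collapses
    photo streams into independent detection events under a configurable
    temporal threshold, computes group-size-weighted encounter rates per
    sampling effort, aggregates them by body-mass class, IUCN Red List
    category and taxonomic group, and derives a relative biomass index.
    Inference uses nested linear mixed-effects models (pairs, concessions
    and cameras as random effects) with BIC-based covariate selection,
    multivariate-t adjusted pairwise contrasts, exact Wilcoxon signed-rank
    tests for paired site summaries, and a habituation (detections-over-time)
    check. Includes a hierarchical synthetic-data generator emulating the
    paired survey design so the whole pipeline is testable without field data.
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
    lme4,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
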