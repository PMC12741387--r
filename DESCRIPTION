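Package: ecofactor
Title: Ecoregion Factors for Biodiversity Weighting in Life Cycle Impact Assessment
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the Ecoregion Factor (EF), a dimensionless weighting
    coefficient expressing the global ecological importance of terrestrial
    ecoregions for biodiversity-aware life cycle impact assessment. Extracts
    four biodiversity indicators per ecoregion (share of grassland and forest,
    share of wetlands, composite global extinction probability, and share of
    roadless area) by zonal statistics over categorical and continuous rasters
    and by polygon overlay, min-max normalizes them, aggregates them with a
    root-mean-square formula into a raw factor, scales the set by its minimum
    into multipliers with baseline 1, aggregates to area-weighted country
    values, and validates the result against a species-richness layer with a
    Spearman rank correlation. Ships a synthetic-world generator producing
    rectangle tessellations and aligned rasters with exactly known ground
    truth, so every pipeline stage is testable against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
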