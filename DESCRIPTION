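Package: carbfact
Title: Fuzzy-Logic Susceptibility Mapping of Marine Carbonate Factories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gridded ecological-niche toolkit for mapping the susceptibility of
    occurrence of the four modern shallow-water marine carbonate factories
    (biochemical, photozoan-T, photo-C and heterozoan-C) from seasonal
    sea-surface temperature, salinity class, marine primary productivity and
    bathymetry. Fuzzy membership functions (Gaussian, near-Gaussian, large
    sigmoid) are calibrated from percentile statistics of observed factory
    footprints, weighted by analytic-hierarchy-process (AHP) factors, masked by
    terrigenous and bathymetric constraints, thresholded per factory and
    combined into a single categorical factory map with the heterozoan-C
    factory acting as opportunistic background. Includes cell-by-cell accuracy
    scoring against observed maps, a deterministic synthetic-world generator
    for download-free testing, plain-text raster IO and a command-line
    workflow.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
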