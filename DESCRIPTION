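Package: yieldscape
Title: Regional Biomass Yield Potentials for Energy Crops from Soil
    Evaluation and Climate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates regional biomass yield potentials for silage maize,
    winter cereals and cup plant from German soil-evaluation records and
    station climate data.  Soil type and soil quality number (Bodenzahl)
    are converted to plant-available field capacity (nFK) through a
    reference-table pedotransfer with fitted interpolation curves; daily
    station climate is aggregated to the monthly values a water- and
    temperature-limited crop growth engine consumes; simulated yields are
    calibrated against observed regional harvest statistics (adjustment
    factor, RMSE, Willmott index of agreement) and transferred back onto
    high-resolution soil maps as per-crop potential surfaces via
    polynomial nFK-yield interpolation curves.  Includes a seeded
    synthetic-data generator emulating a sandy-north/loamy-south region
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
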