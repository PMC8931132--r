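Package: cropshift
Title: Impact of Spatial Cropland Change on Staple-Crop Production Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses how spatial cropland change (urban-adjacent
    contraction versus frontier expansion) alters national staple-crop
    production capacity. Provides a seeded synthetic-landscape generator
    (harvested-area grids at two epochs, weather-station networks, daily
    weather, soils, crop sequences), agro-climatic zonation (growing degree
    days, temperature seasonality, aridity index), a weather-station buffer
    framework with sequential site selection, a simplified daily crop model
    (radiation-use efficiency with a single-layer soil water bucket) for
    irrigated and water-limited annual yield potential, epoch-based area-change
    detection, and area-weighted upscaling to climate-zone and national yield
    ratios and inter-annual yield stability.
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
    purrr,
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
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
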