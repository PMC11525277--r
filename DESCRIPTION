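Package: regcdi
Title: Regional Combined Drought Index from Gridded Land-Surface Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes candidate agricultural-drought indicators (NDWI, NDVI,
    VCI, TCI, SMCI, SMDI, SWDI, SIWSI, SPI) from monthly gridded land-surface
    time series, selects and combines them into a regional combined drought
    index (RegCDI) using per-pixel Shannon-entropy weights, classifies drought
    with USDM-style categories, extracts run-theory drought characteristics
    and hotspot summaries, validates the index against district crop yield
    with confusion-matrix metrics (accuracy, Matthews correlation), and
    evaluates 1-3 month drought early-warning skill. Includes a synthetic
    scene generator emulating a monsoon-regime study area for testing and
    parameter-recovery experiments.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    fitdistrplus,
    ncdf4,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
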