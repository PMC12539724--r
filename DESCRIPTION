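Package: covertrace
Title: Winter Cover-Crop Detection, Crop-Sequence Mining, and Soil Carbon Accounting
Version: 0.1.0
Authors@R:
    person("MAP", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing wintertime cover-crop adoption on
    categorical crop rasters and winter reflectance composites: an NDVI
    threshold filter for contaminated ground-truth points, a pluggable
    binary classifier (built-in random forest or pure threshold rule),
    pixel-wise combination of multi-year crop and cover layers into
    cash-crop/cover-crop sequence tables, county-level zonal accounting
    that splits total adoption into government-subsidized and voluntary
    acreage, and a biomass-partition model of potential soil organic
    carbon sequestration. A synthetic-scene generator provides
    co-registered multi-year rasters, ground-truth points, and subsidy
    ledgers with known truth so every stage is testable without
    satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
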