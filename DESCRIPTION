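Package: lakeFUI
Title: Forel-Ule Water Colour Index Retrieval and Time-Series Aggregation
    for Large Lakes
Version: 0.1.0
Authors@R:
    person("lakeFUI", "Maintainers", email = "maintainers@lakefui.org",
           role = c("aut", "cre"))
Description: Converts multiband surface-reflectance imagery with visible
    (red/green/blue), near-infrared and shortwave-infrared bands plus a
    per-pixel quality bitmask into per-lake Forel-Ule Index (FUI) time
    series. Implements water-leaving reflectance correction by minimum
    NIR-SWIR subtraction, adaptive per-lake water extraction with a
    modified histogram bimodal 1640 nm threshold, CIE-colorimetry FUI
    retrieval through chromaticity hue angle with a band-setting deviation
    correction and a 21-class look-up table, quality-controlled monthly
    and yearly aggregation with temporal and spatial outlier filters, gap
    filling and trend tests, matchup validation statistics, and a
    synthetic-scene generator with known ground truth so the whole chain
    is testable without any satellite download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
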