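Package: vegdyn
Title: Vegetation Dynamics from NDVI Time Series: Trends, Climate-Human
    Attribution, and Persistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel analysis of annual growing-season NDVI raster time
    series: least-squares trend estimation with five-class trend labelling,
    attribution of vegetation change to climate change versus human
    activities by multiple-regression residual analysis with the
    six-condition relative-contribution scheme, and rescaled-range (R/S)
    Hurst-exponent persistence analysis with seven-class labelling,
    combined past-trend x future-persistence classification, and hotspot
    extraction. Includes a synthetic-scenario generator with known
    climate/human structure and an exact fractional-Gaussian-noise
    simulator for validating every stage against ground truth, plus
    plain-text raster (ESRI ASCII grid) input/output, growing-season
    compositing, validity masking, and zonal summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
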