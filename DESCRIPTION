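Package: koppenmap
Title: Koppen-Geiger Climate Classification Maps with Ensemble Confidence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds Koppen-Geiger climate classification maps (5 major classes,
    30 sub-types) from monthly air-temperature and precipitation climatologies.
    Implements the rule-based classifier with aridity-class precedence,
    temporal homogenization and anomaly-method (delta-change) future projection
    via per-month additive offsets and multiplicative factors with bilinear
    coarse-to-fine resampling, ensemble majority voting with per-cell confidence
    levels, categorical raster input/output (single-band uint8 GeoTIFF with
    majority and mean upscaling between the 1/120, 1/12 and 1/2 degree global
    grids), station-based validation with completeness quality control, and a
    synthetic-world generator so the whole pipeline is testable without any
    external climate archive.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
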