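Package: stemscan
Title: Post-Harvest Stem Phenotyping from Submillimetric Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic toolkit for phenotyping cereal stems after
    combine harvest from nadir RGB images with known ground resolution.
    Ingests externally produced stem bounding boxes or detects stem cross
    sections with a matched annulus-template correlator, applies the standard
    detection post-processing (patch tiling with overlap, cross-patch
    duplicate elimination, confidence filtering), measures stem diameters
    from gray-value profiles along four compass directions, and derives
    plot-level traits: stem density, gamma/normal diameter-distribution fits,
    basal area and biovolume. Includes the matching evaluation statistics
    (IOU-matched precision/recall/bias, regression metrics with relative
    RMSE, leave-one-out cross-validated biomass models, broad-sense
    heritability from replicated trials) and a synthetic scene and trial
    generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
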