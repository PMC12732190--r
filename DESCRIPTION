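Package: hemaggr
Title: Hemagglutination Titer Determination from Microplate Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective, image-analysis-based endpoint calling for
    hemagglutination assays photographed on round-bottom 96-well plates.
    Calibrates pixel scale from the manufacturer's well-bottom diameter,
    superimposes a circular region-of-interest grid over the wells,
    thresholds 8-bit grayscale images and measures per-well agglutination
    area and centroid, and classifies wells positive or negative against a
    mean + 3 SD negative-control rule with algorithmic filtering of the
    low-dilution edge-effect artifact. Includes serial-dilution bookkeeping
    (per-well analyte mass, hemagglutination units, minimum-detectable-amount
    concentration estimates for lectins such as phytohemagglutinin),
    linear ELISA standard-curve quantitation with censoring at the lower
    limit of quantification, exposure-dose arithmetic, and a seeded
    synthetic plate-photograph renderer with ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
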