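Package: phenomspec
Title: Plant-Level Phenotyping from Multispectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for monitoring individual plants with a four-band
    multispectral camera (green, red, red edge, near infrared): integer-pixel
    band registration and area-of-interest clipping, per-pixel vegetation
    indices (NDVI, OSAVI, MSR and eight others), NDVI-percentile plant
    segmentation with largest-component filtering, twelve binary shape
    descriptors with regionprops semantics, and a treatment-discrimination
    statistics layer (one-way ANOVA, Tukey HSD, growth-curve regression,
    functional boxplots). Includes a synthetic scene and trial generator with
    known ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    png,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
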