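Package: mcsgrad
Title: Front-Back Gradient Quantification of ER-PM Contact Sites in Migrating Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for membrane contact site puncta in
    time-lapse fluorescence movies of cells migrating on micropatterned stripes.
    Provides a ground-truthed synthetic movie generator, nuclear and whole-cell
    segmentation, nearest-neighbour cell and puncta tracking with lifetime and
    mass statistics, cell-frame flow fields, 20-bin front-to-back gradient
    profiles and kymographs, polarity-steepness scores, growth-rate slope
    analysis, and mean-squared-displacement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
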