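Package: isletquant
Title: Semiautomated Quantification of Pancreatic Islet Cell Masses from
    Dual-Channel Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-islet morphometry of pancreatic endocrine cell masses from
    dual-channel immunofluorescence sections: channel splitting and mutual
    red/green bleed-through correction, per-islet Otsu (between-class
    variance) segmentation of the insulin channel and Kapur (maximum
    entropy) segmentation of the somatostatin channel, area and
    equivalent-diameter morphometry with size-class counting, and
    per-animal aggregation.  Companion islet-assay normalizations are
    included: fold-over-basal secretion, stimulation index as a percentage
    of hormone content, four-parameter logistic EC50 fitting, delta-Ct
    relative expression, and fura-2 ratio (delta F340/F380) quantification.
    A seeded synthetic-data generator produces dual-channel islet images
    and assay tables with known ground truth so every stage is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
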