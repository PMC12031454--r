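Package: mangroveseg
Title: Attention-Based Segmentation of Mangrove Extent and Species from
    Multispectral UAV Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping mangrove forests from 5-band (Blue, Green,
    Red, RedEdge, NIR) unmanned-aerial-vehicle rasters. Implements a
    parallel spectral/spatial attention block, the MangroveNet multi-scale
    encoder-decoder for binary extent segmentation, the AttCloudNet+
    network for 4-class species identification trained with a filtered
    Jaccard loss, deterministic 512x512 tiling with 150-pixel overlap and
    mosaicking, a confusion-matrix evaluation suite (accuracy, precision,
    recall, F1, mIoU, Cohen's kappa with qualitative bands, overall
    accuracy), pixel-based area quantification, and a seeded synthetic
    multispectral scene generator for end-to-end testing. Networks are
    trained with a compact reverse-mode automatic-differentiation engine
    backed by compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
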