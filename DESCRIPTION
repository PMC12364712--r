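Package: plexgen
Title: Generating Spatially Resolved Protein Multiplexes from H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional generative translation of haematoxylin-and-eosin (H&E)
    histology images into multi-channel protein-marker images, together with the
    surrounding analysis pipeline: imaging-mass-cytometry style marker
    normalization, mutual-information template matching of serial-section
    regions of interest, Macenko stain normalization, tile-based whole-slide
    inference with stitching, full-reference image metrics (PSNR, MS-SSIM,
    sliding-window RMSE), pseudo-cell extraction with random-forest cell typing
    and Spearman co-localization analysis, CD8 density based immune phenotyping,
    and attention-based multiple-instance learning with discrete-time survival
    heads and optional co-attention multimodal fusion. A built-in tissue
    simulator produces paired pseudo-H&E/marker images, cell tables, region
    masks and survival bags with known ground truth, so the whole pipeline runs
    at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    survival,
    ranger,
    pROC,
    Rtsne,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
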