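Package: polypseg
Title: Modified SegNet Encoder-Decoder Networks for Polyp Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, trains and evaluates a family of modified SegNet
    VGG-19 encoder-decoder convolutional networks for binary polyp
    segmentation in colonoscopy frames.  The modifications are additive
    skip connections between mirrored encoder and decoder depths, extra
    5x5 convolution blocks at the two shallowest depths, and a parallel
    dilated-convolution pyramid (dilations 1/6/12/18) at the encoder
    bottleneck.  Includes the momentum-SGD training protocol with a
    piecewise-constant learning-rate schedule, index-passing max
    unpooling, the pixel-wise evaluation suite (accuracy, sensitivity,
    specificity, precision, class IoU, Dice, F2), CVC-style image/mask
    dataset handling with a pooled 70/30 split, and a procedural
    generator of colonoscopy-like image/mask fixtures so every component
    is testable at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    generics,
    rlang,
    withr,
    jsonlite,
    yaml,
    png,
    tiff,
    optparse,
    ggplot2,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
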