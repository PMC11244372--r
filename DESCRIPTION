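Package: tongueseg
Title: Tongue Image Segmentation with 2D Structured State-Space Convolutional Attention
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of tongue photographs taken with consumer
    phone cameras, for Traditional Chinese Medicine tongue diagnosis pipelines.
    Implements a four-stage convolutional-attention encoder in the SegNeXt
    style whose attention blocks carry a two-dimensional structured
    state-space (S4) layer in place of the usual 1x1 convolution, a UNETR-like
    skip-connection decoder with progressive upsampling, cross-entropy and
    boundary losses, Dice/mIoU/pixel-accuracy evaluation, and a seeded
    synthetic tongue-scene generator so that the full train/evaluate loop runs
    at desk scale without any clinical data. Forward and backward passes are
    implemented natively (no external deep-learning framework) with compiled
    kernels for the convolution and state-space primitives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
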