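Package: lwseg
Title: Lightweight Encoder-Decoder Networks for Rice Seedling Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lightweight encoder-decoder convolutional networks (LW-Segnet and
    LW-Unet) for pixel-wise segmentation of rice seedling stands and seedling
    rows in 5-band multispectral UAV imagery. Implements the lightweight
    hybrid attention (LHA) module, separable spatial pyramid dilated
    convolution (SSPDC), SegNet-style max-pooling-index unpooling, bilinear
    upsampling, a weighted focal binary cross-entropy loss, pixel-wise
    evaluation metrics, an analytic parameter and FLOP profiler, a
    multispectral tiling and splitting pipeline, and a procedural generator
    of synthetic paddy-field tiles with paired ground-truth masks. Networks
    are trained with Adam via backpropagation implemented natively on BLAS
    matrix operations; no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
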