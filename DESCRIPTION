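Package: fissureseg
Title: Semantic Segmentation of Fissured Tongue Images with a Large-Kernel U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Encoder-decoder semantic segmentation of thin crack structures
    in tongue images. Implements an improved U-Net whose encoder is an
    Inception-style backbone and whose skip pathways pass through
    large-kernel Global Convolutional Network (GCN) modules, in dense and
    depthwise-separable variants, followed by Boundary Refinement (BR)
    residual blocks. Ships a self-contained CPU training engine
    (convolution, batch normalization, transposed-convolution and bilinear
    upsampling kernels with analytic gradients, Adam optimizer), a
    synthetic fissured-tongue image generator with pixel-exact ground
    truth, flip/rotation (dihedral orbit) and random-crop augmentation,
    confusion-matrix metrics (pixel accuracy, per-class IoU, MIoU), an
    ablation harness comparing encoder and module choices, and an
    end-to-end reproducible experiment pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
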