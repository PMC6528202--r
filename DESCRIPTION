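Package: mcmlfundus
Title: Multi-Channel Landmark-Conditioned Synthesis of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of color retinal fundus photographs from binary
    landmark masks (vessel tree, optic disc, optic cup) with conditional
    adversarial image-to-image models.  Composes the three masks into a
    multi-channel conditioning input, trains paired (Pix2pix-style) or
    unpaired (cycle-consistent) translation models with U-net, ResNet-6/9
    or residual-U-net generators and a convolutional patch discriminator,
    and evaluates synthesized images with SSIM and PSNR.  A procedural
    fundus-phantom simulator generates paired mask/image data with exact
    ground truth, so the full pipeline runs end to end without external
    datasets.  The convolutional network engine (forward/backward
    convolution, normalization, Adam) is implemented in the package with
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
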