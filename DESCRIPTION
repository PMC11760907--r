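Package: vesselStack
Title: Stacked Ensemble Deep Learning for Retinal Blood Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise segmentation of retinal blood vessels in fundus
    photographs with four customized encoder-decoder networks (U-Net, a
    ResNet50 segmentation variant with a dilated-convolution pyramid pooling
    module, U-Net with a ResNet50 backbone, and a U-Net with a transformer
    bottleneck) fused by a convolutional stacking meta-model. Includes a
    compact reverse-mode automatic-differentiation engine with Armadillo
    convolution kernels, the full pixel-wise evaluation suite (accuracy,
    sensitivity, specificity, F1, AUC, binary cross-entropy), DRIVE/STARE-style
    dataset handling, a synthetic fundus/vessel-tree generator with exact
    ground truth, on-the-fly augmentation, and a reproducible training and
    ablation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
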