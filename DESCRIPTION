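Package: digcsvnet
Title: Lung Nodule Segmentation with Pixel-Threshold Feature Separation
    and 3D Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric segmentation of pulmonary nodules in thoracic CT with a
    V-Net style encoder-decoder whose input layer decomposes the windowed image
    into pixel-threshold (bit-plane) feature maps and whose downsampling stages
    end in a 3D convolutional block attention module (channel plus spatial
    attention). Includes CT volume and annotation input/output (MetaImage and
    NIfTI), preprocessing of cases into 96x96x16 nodule cubes, label
    rasterization from annotations, volumetric data augmentation, cross-entropy
    training with Adam and a plateau learning-rate schedule, ten-fold
    cross-validation, Dice/IoU/sensitivity/PPV evaluation, an ablation harness,
    and a synthetic CT phantom generator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
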