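Package: daunet
Title: Dense Convolutional Attention U-Net for Intracranial Aneurysm
    Segmentation in TOF-MRA Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and applies a three-dimensional dense convolutional
    attention U-Net for voxelwise segmentation of intracranial aneurysms in
    time-of-flight magnetic resonance angiography (TOF-MRA) volumes. The
    encoder combines pre-activation dense blocks with convolutional block
    attention (channel then spatial gating); the decoder fuses skip
    connections and a multiscale fusion head that upsamples and merges
    feature maps from several resolutions before classification. Includes
    NIfTI input/output, aneurysm-centred patch extraction with z-score
    normalisation and flip/intensity augmentation, a Dice plus cross-entropy
    compound loss, Adam optimisation with plateau learning-rate decay,
    voxelwise evaluation metrics (Dice, sensitivity, specificity, precision)
    with lesion-size stratification, and a synthetic vascular-phantom
    generator so that the whole train/predict/evaluate loop runs without any
    external dataset. All tensor operations (3D convolution, transposed
    convolution, pooling, trilinear upsampling) and reverse-mode gradients
    are implemented natively in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    readr,
    jsonlite,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
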