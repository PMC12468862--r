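Package: cxreffusion
Title: Costophrenic-Angle Cropping, Enhancement and Evaluation for
    Pleural-Effusion Screening in Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated image-analysis pipeline for detecting pleural
    effusion on frontal chest radiographs. Implements lung-field cropping
    from projection profiles of a binary lung mask (grayscale conversion,
    negative transform, adaptive histogram equalization, thresholding and
    morphological cleanup), extraction of the heart-to-costophrenic-angle
    region of interest normalized to 227x227 pixels, a two-stage
    enhancement step (histogram stretching plus Sobel gradient edge
    blending, with logarithmic, CLAHE, sharpening and Canny alternates),
    a synthetic radiograph phantom generator with ground-truth geometry,
    and an evaluation harness with confusion-matrix metrics, stratified
    splits, k-fold cross-validation and pluggable classifier backends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
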