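Package: fundusHem
Title: Retinal Hemorrhage Detection in Fundus Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An eight-stage pipeline for detecting retinal hemorrhages in
    color fundus photographs of diabetic-retinopathy patients. Stages:
    green-channel extraction; a modified contrast-limited adaptive histogram
    equalization (CLAHE) with per-tile Rayleigh intensity remapping and
    linear stretching; a patch-based convolutional network for per-pixel
    hemorrhage segmentation with Otsu field-of-view estimation and
    morphological cleanup; VGG19-style deep-feature extraction with a
    transfer-learning head; sparse multinomial-logistic feature selection
    (MRCEV); convolutional sparse feature fusion (CSID); an extreme learning
    machine classifier with ridge-stabilized output weights; and a full
    evaluation battery (confusion metrics, ROC/AUC, confidence intervals,
    replicate averaging). Includes a seeded synthetic fundus generator with
    ground-truth masks so the whole pipeline is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
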