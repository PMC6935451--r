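Package: thermoseg
Title: Curvature-Initialized Gradient Vector Flow Segmentation and
    Asymmetry-Based Classification of Breast Thermograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segments the left and right breast in pseudo-colour
    thermographic images using curvature-function analysis of the body
    silhouette to place elliptical initial contours, followed by a
    Gradient Vector Flow (GVF) active contour (snake).  From the two
    segmented regions it extracts a 155-dimension feature vector (shape,
    first-order and co-occurrence texture per colour channel, and
    left-right bilateral asymmetry relations) and classifies images as
    normal or abnormal with a small convolutional network or standard
    feature-based learners under stratified 2-fold cross-validation.
    Includes a seeded synthetic thermogram phantom generator with ground
    truth masks, segmentation agreement (Zijdenbos/Dice) and a full set
    of confusion-matrix quality indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
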