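Package: cropcam
Title: Weakly Supervised Crop-Area Segmentation and Uncut-Edge Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments the uncut crop area in combine-harvester front-view
    scenes without pixel-level labels. A shallow four-layer convolutional
    classifier with a global-average-pooling head is trained on class-pure
    image patches (uncut crop, harvested stubble, background); its class
    activation maps segment the crop area of a full scene, and geometric
    post-processing (contour extraction, vertical trimming, rightmost-pixel
    filtering, Hough voting) reduces the area to a single straight
    uncut-crop-edge guidance line. Includes a synthetic field-scene
    generator with pixel-perfect ground truth, an image-patch-classification
    baseline, and evaluation by intersection-over-union, lateral error and
    angular error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
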