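Package: whalepassport
Title: Automated Photo Identification of Right Whales via Passport Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for individual identification of North
    Atlantic right whales from overhead photographs. A convolutional network
    localizes the whale's head in a downscaled image, a second network locates
    two anatomical keypoints (the tip of the bonnet and a point just below the
    blowholes), a two-point similarity transform rotates, scales and crops the
    photograph into a standardized "passport photo", and a third network with
    an auxiliary callosity-connectivity head assigns the image to an individual.
    Includes a synthetic-scene generator with known ground truth, prediction
    averaging across network ensembles, and competition-style evaluation with
    clipped multiclass log loss, top-1 and top-5 accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
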