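Package: gingershift
Title: Cross-Device Identification of Sulfur-Fumigated Ginger from Phone Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies sulfur-fumigated ginger from ordinary smartphone
    photographs and adapts the classifier to images from an unseen camera
    device. Provides a synthetic device-shift image generator (four camera
    profiles with distinct resolution, colour balance, saturation, gamma and
    sensor noise), region-proposal based specimen cropping, image
    standardization transforms, a hybrid 18-layer residual backbone plus
    fully connected head trained with mean-squared-error loss, a
    support/query episodic meta-optimizer with moment-based (Adam-style)
    updates and fine-tuning on a held-out device, and an evaluation harness
    (precision, recall, F1, ROC-AUC, accuracy, repeated random splits,
    training-ratio sweeps). All neural-network forward and backward passes
    are implemented in the package with RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
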