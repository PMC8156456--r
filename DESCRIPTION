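Package: csagnet
Title: Attention-Guided Filter Networks for Skin Lesion Segmentation
Version: 0.1.0
Authors@R: person("csagnet", "maintainers", email = "csagnet@example.org",
    role = c("aut", "cre"))
Description: Encoder-decoder convolutional networks for dermoscopy lesion
    segmentation built around a channel-spatial fast attention-guided filter
    (CSFAG) embedded in the skip connections, a densely connected bottleneck,
    pyramid inputs and averaged side outputs.  Includes the exact
    preprocessing and 8-fold augmentation pipeline, confusion-matrix
    evaluation metrics, a deterministic synthetic dermoscopy generator for
    desk-scale testing, CPU training with momentum SGD, and exact trainable
    parameter accounting for the five architecture variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, jsonlite
SystemRequirements: zlib
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
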