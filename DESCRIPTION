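Package: spo2cam
Title: Semi-Supervised Video-Based Estimation of Peripheral Oxygen Saturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates peripheral oxygen saturation (SpO2) from ordinary RGB
    video of skin regions (face and hand) via remote photoplethysmography
    (rPPG). A 3D convolutional network maps spatiotemporal video blocks to
    multi-channel pulse signals; it is pre-trained with contrastive losses
    built on the similarity of power spectral densities across body regions
    and fine-tuned against reference photoplethysmograms. A CNN-BiLSTM head
    and a manual-feature attention module are fused under a constrained
    attention weighting to produce per-window SpO2 estimates. Includes a
    synthetic pulsatile-video generator with a ratio-of-ratios ground-truth
    encoding so the whole pipeline is testable without clinical recordings,
    plus leave-one-subject-out evaluation and ablation tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rlang,
    tibble,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
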