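Package: ablamark
Title: Deformable Registration-Based Ablative Margin Assessment for
    Hepatic Thermal Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the ablative margin after image-guided thermal
    ablation of liver tumours. Implements an unsupervised deformable
    image registration of pre- and post-ablation volumes built on a
    Siamese spatial transformer (control-lattice displacement field,
    differentiable tent-kernel sampler) driven by a block-wise
    normalized cross-correlation loss on deep multiscale convolutional
    features; spacing-aware signed surface-distance computation of the
    minimal ablative margin with 5-mm safety classification; synthetic
    phantom image pairs with ground-truth deformations and synthetic
    survival cohorts; and the downstream local-tumour-progression
    statistics (Kaplan-Meier, log-rank, forward-stepwise Cox
    proportional hazards, DeLong comparison of correlated ROC curves).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    survival
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
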