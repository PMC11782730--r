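Package: ptxmap
Title: Complex-Valued Neural B1+ Mapping and Parallel-Transmit Pulse Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep-learning based calibration chain for ultra-high-field (7T)
    parallel transmission. Complex-valued encoder-decoder networks map
    multi-channel CP+-mode localizer images to channel-wise transmit-field
    (B1+) maps; downstream consumers design static phase-only RF shims and
    dynamic kt-point pulses and verify them with hard-pulse Bloch
    simulations. Ships an analytic 8-channel transceiver-coil head-phantom
    simulator that generates paired localizer/B1+ libraries for training and
    evaluation, the complex network primitives (complex convolutions,
    ModReLU, complex Glorot initialisation, perpendicular + L2 loss) with
    hand-verified backpropagation, subject-wise cross-validation, and the
    field's B1+ quality metrics (relative magnitude error, circular phase
    difference, RMSE, magnitude/phase/complex SSIM, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    yaml,
    jsonlite,
    optparse,
    RNifti,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
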