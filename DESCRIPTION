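Package: condiff
Title: Guided Conditional Diffusion Classification of Wound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distance-based image classification with guided conditional
    diffusion models. A two-class image is partially noised, denoised twice
    under each class condition with classifier-free-guided DDIM sampling, and
    assigned the label whose synthesis lies closest to the original image in
    a triplet-loss-trained embedding space. Includes the full two-stage
    training pipeline (conditional denoiser, metric-learning embedding),
    Score-CAM similarity heatmaps, a synthetic two-class wound-image
    generator with subject-wise anti-leakage splitting, and an evaluation
    harness (confusion metrics, k-fold cross-validation, noise-strength
    sweeps, inter-condition divergence diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
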