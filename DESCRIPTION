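Package: ldctloss
Title: Adaptive Patch-Weighted and High-Frequency Hybrid Loss for Low-Dose CT Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating low-dose CT (LDCT) denoisers with a
    hybrid loss that combines an adaptive weighted patch loss (per-patch mean
    absolute error scaled by median-normalized, clamped weights) with a
    high-frequency loss (mean absolute difference of DFT high-pass filtered
    images). Includes a parallel-beam Radon transform and filtered
    back-projection, projection-domain Poisson quantum-noise simulation of
    low-dose acquisitions, PSNR/SSIM image-quality metrics with region-of-
    interest variants, a deterministic synthetic CT phantom generator, and a
    small residual convolutional denoiser (Rcpp backend) used as a reference
    training harness for loss-function ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
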