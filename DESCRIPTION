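Package: nativenoise
Title: Native Noise Denoising for Low-Field MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Rician noise of very low-field MRI by iterative
    SNR-matched noise injection into the complex domain of high-field
    magnitude images, builds paired noisy/clean patch datasets, trains a
    small U-Net denoising autoencoder (implemented natively with
    Rcpp/RcppArmadillo convolution primitives), and evaluates denoising with
    corner-patch SNR, PSNR, SSIM, paired statistics, difference maps, line
    profiles and effective receptive fields. Includes a seeded synthetic
    image generator (brain-like slices and structured phantoms) so the whole
    pipeline is testable without external MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
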