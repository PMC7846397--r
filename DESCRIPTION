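Package: rwsdip
Title: Reference-Driven Wavelet-Sparsity Deep Image Prior for Undersampled MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-scan reconstruction of undersampled magnetic resonance images
    with an untrained convolutional encoder-decoder ("deep image prior"). A
    structurally similar high-resolution reference image drives the network,
    and training is cast as a wavelet-sparsity constrained optimisation solved
    by ADMM: a gradient-based network update, a closed-form soft-thresholding
    update of the wavelet code, and a dual ascent on the multiplier. A final
    k-space data-correction step re-inserts all acquired Fourier samples.
    Includes the zero-filling and noise-input deep-image-prior baselines,
    Cartesian/radial/variable-density sampling-mask generators, an ellipse
    phantom generator for reference/target pairs, RelErr/PSNR/SSIM metrics,
    and an experiment runner for comparison, convergence and parameter-sweep
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    rhdf5,
    png,
    optparse
Config/testthat/edition: 3
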