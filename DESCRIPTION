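Package: mfecg
Title: Multiscale Entropy and Multifractal Features for ECG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity analysis of electrocardiogram (ECG) recordings for
    discriminating congestive heart failure from normal sinus rhythm.
    Implements generalized multiscale sample entropy with first-moment
    (mean) and second-moment (unbiased variance) coarse-graining,
    wavelet-leader multifractal analysis (structure functions, scaling
    function, Legendre and direct singularity spectra, uniform Hoelder
    bounds), wavelet denoising of raw ECG segments, an extreme learning
    machine classifier trained by least squares, stratified k-fold
    evaluation with the standard confusion-matrix metric suite, and
    seeded generators for synthetic validation signals (white and 1/f
    noise, binomial cascades, fractional Brownian motion, and two-class
    ECG-like cohorts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    class,
    optparse
Config/testthat/edition: 3
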