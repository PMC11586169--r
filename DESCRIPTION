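Package: specselect
Title: Wavelength Selection and PLSR Calibration for Vis-NIR Transmission Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building soluble-solids-content (SSC) calibration models from
    visible/near-infrared full-transmission spectra of fruit. Implements spectral
    preprocessing (edge-frame truncation, multi-frame averaging, Gaussian filtering,
    standard normal variate, multiplicative scatter correction), NIPALS partial least
    squares regression with latent-variable selection by cross-validated RMSECV,
    Monte-Carlo outlier detection, spectral binning, backward variable selection
    (BVS-PLS), simulated-annealing subset refinement, and an end-to-end reproducible
    pipeline. Includes a synthetic Beer-Lambert transmission-spectra generator with
    known ground truth for validating wavelength-recovery performance.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
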