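Package: vipabrill
Title: Automated Analysis of VIPA Brillouin Spectrometer Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated retrieval of Brillouin line-shape parameters
    from two-dimensional frames acquired with a dual-stage virtually imaged
    phase array (VIPA) spectrometer. Provides contrast normalization for
    display, automatic sub-pixel localization of the four saturated Rayleigh
    peaks, homography-based drift correction onto a canonical square, spectral
    extraction by column-maximum projection along the dispersion diagonal,
    pixel-to-frequency calibration from the free spectral range, local-mean
    peak segmentation, and Lorentzian/Gaussian nonlinear least-squares fitting
    with RMS and R-squared quality metrics. A synthetic frame generator with
    complete ground truth supports validation of every stage, and a small
    command-line interface covers simulation, registration, extraction,
    fitting and hyperspectral map assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    grDevices,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
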