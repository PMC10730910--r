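Package: segwave
Title: Segmented Multifocal Wavefronts and Through-Focus Visual Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Converts radial sagittal power profiles of multifocal contact and
    intraocular lenses into segmented multifocal wavefronts, superposes
    measured ocular higher-order aberrations, and scores the combination
    through focus with a neural contrast-sensitivity-weighted visual Strehl
    ratio (VSOTF).  Provides annular pupil segmentation, OSA-convention
    Zernike wavefront synthesis, a Fourier-optics PSF/OTF engine, through-focus
    comparison metrics (area under the curve, range above threshold, peak
    performance) with monofocal normalization, and a synthetic generator for
    lens designs and eye populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
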