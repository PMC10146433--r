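Package: herbscreen
Title: Multidimensional Chromatographic Fingerprint Screening of Botanical
    Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Chemometric screening of regulated plants in complex herbal
    mixtures from liquid-chromatography diode-array-detection (LC-DAD) data
    cubes. Implements correlation-based selection of orthogonal detection
    wavelengths, correlation-optimized warping (COW) of chromatograms by
    dynamic programming, sample-wise unfolding of three-way data, the duplex
    algorithm for representative calibration/validation splitting, and
    PLS-DA classification (NIPALS) with stratified 10-fold cross-validation
    for latent-variable selection. Ships a synthetic LC-DAD study generator
    (Gaussian peaks, compound UV spectra, Beer-Lambert mixing, retention
    jitter) emulating a spiked-trituration study design, plus an end-to-end
    training and screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
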