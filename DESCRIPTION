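Package: imcseg
Title: Density-Based Single-Cell Segmentation and Marker Quantification
    for Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-cell segmentation and per-cell marker quantification for
    imaging mass cytometry (IMC) regions of interest. Implements hot-pixel
    removal, Gaussian-blur background subtraction, a percentile weight
    transform, weighted DBSCAN pixel clustering with local-maxima cluster
    splitting, marker-overlap cell typing (CD31/Vimentin), binary erosion and
    area filtering, per-cell mean intensities with the arcsinh cofactor
    transform, and two-group per-cell comparisons with Welch t-tests and
    Tukey violin summaries. A synthetic multiplexed-image generator with
    known ground truth (cell centers, types, amplitudes, label masks) makes
    every stage verifiable without patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
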