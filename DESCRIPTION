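Package: boutonCI
Title: Object-Based 3D Colocalization and Soma-Size Mixture Analysis for
    Laminar Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies cross-channel colocalization of axonal boutons in
    two-channel 3D fluorescence stacks using an object-based
    nearest-neighbor statistic: objects are segmented by smoothing,
    thresholding and connected-component labeling, reduced to centroids and
    equivalent-sphere radii, and two objects are called colocalized when
    their interbouton distance (center distance minus both radii) is
    negative.  A per-image Colocalization Index (CI) normalizes the
    percentage of candidate-channel objects containing the reference marker
    by the percentage of reference-channel objects containing the candidate
    marker.  Also provides univariate Gaussian mixture modeling of cell
    soma sizes with BIC model selection and per-cell classification, the
    group-comparison statistics used alongside these analyses, a synthetic
    ground-truth scene generator for end-to-end validation, and YAML-driven
    pipeline runners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
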