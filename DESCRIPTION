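Package: seegrs
Title: Recording-Sensitivity Modelling and Optimization of Stereo-EEG Electrode Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spatial recording sensitivity of stereo-EEG depth
    electrodes and optimizes electrode configurations for user-defined
    cortical regions of interest. Provides parametric synthetic head
    geometry (scalp, inner skull, folded cortex), an analytic current-dipole
    forward model with an import path for externally computed lead fields,
    extended cortical patch sources of fixed area and dipole moment density,
    a recording-sensitivity metric with recording-radius estimation,
    safety-constrained electrode trajectory generation (insertion angle,
    length, sulci/skull/midline clearance, pairwise collisions), and a
    greedy next-best search that adds the electrode maximally reducing the
    number of unrecordable sources at a priority detection threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
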