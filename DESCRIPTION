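Package: retinotune
Title: Orientation Tuning and Dynamic Predictive Coding Analysis for
    Synaptic Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing two-photon fluorescence
    recordings of synaptic activity in the retina: rendering of
    contrast-reversing grating, moving-bar and flashed-bar stimulus
    protocols; simulation of ground-truth populations of bipolar cell
    terminals and of fluorescence movies; correlation-seeded region-of-
    interest segmentation; orientation-selectivity statistics including a
    rank-based Moore-Rayleigh test with shuffle-calibrated significance;
    receptive-field reconstruction by filtered back projection with
    2D-Gaussian fitting and an ellipticity-to-OSI forward model; and a
    conductance-based feedforward-inhibition model of retinal ganglion
    cell output with NLMS system identification of its temporal filter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    signal,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
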