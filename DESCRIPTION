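Package: ssasim
Title: Simulation and Analysis of Stimulus-Specific Adaptation in Auditory
    Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construct oddball, repeated-adaptation (RAP), forward-suppression
    and frequency-response-area (FRA) stimulus protocols; simulate inferior
    colliculus-like single units through a level-dependent cochlear filterbank
    front end feeding frequency-tuned synapses with activity-dependent
    depression; generate Poisson spike trains with drive-dependent first-spike
    latency; and compute the standard stimulus-specific adaptation measures
    (CSI, SI, NRI, monotonicity index), peri-stimulus time histograms,
    frequency suppression areas, and nonlinear least-squares fits of the
    adaptation function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
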