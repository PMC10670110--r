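Package: swnf
Title: Small-World Brain-Network Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for functional near-infrared
    spectroscopy (fNIRS) neurofeedback experiments that target the
    small-world organization of frontal functional brain networks. Provides
    a synthetic-data generator (latent Watts-Strogatz graphs, multichannel
    hemodynamic signals, raw optical intensities, multi-day training
    cohorts, and Stroop behavioral data), offline and online-capable
    preprocessing (optical density, motion detection, spline correction,
    Butterworth band-pass, modified Beer-Lambert inversion), sliding-window
    Fisher-z connectivity graphs with sparsity thresholding, small-world
    metrics normalized against degree-preserving random nulls, the
    baseline-normalized real-time feedback score, Stroop-task scoring, the
    design's inferential statistics (including an a-priori repeated-measures
    ANOVA power computation), and higher-order topology analyses such as
    edge reallocation and placement on the Watts-Strogatz rewiring
    continuum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
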