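Package: skan
Title: Synapto-Dendritic Kernel Adapting Neurons for Spike Pattern Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time simulation and analysis of multiplier-free spiking
    neurons whose adaptive triangular synapto-dendritic kernels and homeostatic
    thresholds perform unsupervised learning of spatio-temporal spike patterns,
    statistical inference over inter-spike intervals, and, with a single global
    decaying inhibitory bit, competitive winner-take-all classification.
    Includes seeded generators for jittered, corrupted and drifting spike
    stimuli, temporal receptive-field probing, and Monte-Carlo experiment
    harnesses for selection, classification-convergence and noise-robustness
    studies. All state is integer-valued, so runs are bit-exact reproducible.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
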