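Package: aimnet
Title: Attentional Inhibitory Modulation in a Spiking Model of Auditory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a spiking cortical circuit in which selective auditory
    attention is implemented as top-down control of a second inhibitory
    population that gates lateral inhibition (attentional inhibitory
    modulation). Provides a leaky integrate-and-fire network simulator with
    double-exponential conductance synapses, spatial and spectral network
    builders with Gaussian and thresholded inverted-Gaussian connectivity
    kernels, a subcortical auditory front-end (gammatone filterbank on an
    ERB-spaced grid, parametric interaural time and level cues, binaural
    spatial segregation, inhomogeneous Poisson spike encoding), analysis
    tools (moving-window PSTHs, tuning surfaces, 2-D correlations, pitch
    estimation), and scripted protocols that reproduce attentional
    sharpening, suppression, receptive-field hotspot emergence and
    cocktail-party monitor, select and switch behaviour.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
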