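Package: tcmdbs
Title: Thalamocortical Spiking-Network Simulation of Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates a six-population spiking thalamocortical
    microcircuit of the Parkinsonian motor system under deep brain
    stimulation (DBS). Izhikevich neurons with noisy thresholds are
    coupled through Tsodyks-Markram short-term-plasticity synapses with
    transmission delays; stimulation is delivered as intracellular pulse
    trains (conventional periodic DBS plus two minimal-stimulus burst
    patterns) to half of the deep cortical layer. Includes local field
    potential estimation from postsynaptic currents, Welch spectral
    analysis of beta-band (13-30 Hz) power and its attenuation, an
    SVD-based covariance-complexity synchrony index, an amplitude
    calibration routine, a repeated-protocol experiment runner with
    statistical comparison, and controlled synthetic fixtures for the
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
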