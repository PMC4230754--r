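Package: nmstand
Title: Biologically Based Neuromusculoskeletal Simulation of Human Quiet Standing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation of human upright quiet stance built from
    spinal physiology: pools of type-specified two-compartment motor neurons and
    point interneurons with kinetic synapses, Hill-type musculotendon models of
    the ankle plantar flexors (soleus, medial and lateral gastrocnemius) and
    dorsiflexor (tibialis anterior), muscle spindle (bag1/bag2/chain) and Golgi
    tendon organ receptor models feeding back Ia, II and Ib afferent spike
    trains, and a single-link inverted pendulum of the body about the ankle.
    Includes stochastic gamma point-process generators for descending drive and
    afferent encoding, phenomenological surface EMG synthesis, and the
    posturography and motor-unit analysis battery used in quiet-stance studies
    (centre-of-pressure metrics, cross-correlations, activation ratios,
    inter-recruitment intervals, recruitment phase plots, windowed fibre-length
    correlations, and a Jarque-Bera bimodality test on centre-of-mass
    histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
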