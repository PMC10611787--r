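Package: threatmap
Title: Analysis of Aversive-Stimulus Coding in Hippocampal CA1 Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for head-fixed treadmill electrophysiology sessions
    that characterizes how aversive stimuli (air puffs, tail shocks) reshape
    the hippocampal spatial code. Starting from sorted spike trains, a
    behavior trace, an event log and a pyramidal-layer LFP channel, the
    package classifies units into putative pyramidal cells and interneurons,
    detects stimulus-locked activation and suppression from z-scored
    peri-stimulus histograms, builds occupancy-normalized tuning curves with
    place-field detection and spatial information, infers putative
    monosynaptic pyramidal-to-interneuron connections from cross-correlograms
    with a partially hollow Gaussian predictor, detects sharp-wave ripples
    and theta phase (including circular-linear phase-precession fits),
    extracts co-activation assemblies by PCA/ICA with a Marcenko-Pastur
    component threshold, and decodes position from theta-cycle spike counts
    with a Poisson Bayesian decoder, including reward-zone shift analysis
    with a Monte-Carlo null. A synthetic-session generator with full ground
    truth makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
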