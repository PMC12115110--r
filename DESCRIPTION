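Package: eegkin
Title: Time-Frequency Analysis of EEG Energy and Ankle Kinematics for Motor-Imagery BMIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coupling between band-limited
    electroencephalographic (EEG) instantaneous energy density and ankle
    kinematics during exoskeleton-driven plantar/dorsal flexion, and for
    decoding motor imagery from the same energy features. Implements four
    time-frequency energy estimators (short-time Fourier, Stockwell,
    variational mode decomposition with Hilbert demodulation, and chirplet),
    causal preprocessing (state-space Butterworth high-pass, H-infinity
    ocular-artifact suppression, maximum-visual-threshold normalization),
    data-driven frequency-band derivation from intrinsic-mode instantaneous
    frequencies, lagged cross-correlation analysis between EEG energy and
    joint angle, a compact convolutional motor-imagery classifier with
    leave-one-trial-out validation, and the accompanying non-parametric
    statistical battery. A synthetic session generator with known ground
    truth (injected energy-kinematics lag, configurable event-related
    desynchronization) makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
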