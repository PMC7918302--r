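Package: ptesleep
Title: Sleep Architecture and Epileptiform Event Analytics for Rodent EEG
Version: 0.1.0
Authors@R:
    person("PTE", "Sleep Analytics Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: An end-to-end pipeline for characterizing sleep-wake disturbance
    and interictal epileptiform activity in rodent EEG/EMG recordings, as
    used in controlled-cortical-impact models of post-traumatic epilepsy.
    Provides EDF reading and writing, zero-phase Chebyshev filtering,
    amplitude-threshold detection of high-amplitude interictal events with
    principal-component Gaussian-mixture waveform clustering and
    injury-specificity scoring, hypnogram-based sleep architecture metrics,
    cubed-RMS sigma-band sleep spindle detection, per-epoch normalized NREM
    delta power, the associated group statistics (one-way and split-plot
    ANOVA, Welch t tests with Bonferroni correction, Tukey-Kramer
    comparisons), and a synthetic EEG/EMG cohort generator with exact ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
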