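Package: phaseconn
Title: Time-Resolved Phase Coherence and Coupling Analysis for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-localized, phase-based connectivity analysis for multichannel
    resting-state EEG. Implements the continuous Morlet wavelet transform on a
    logarithmic frequency grid with cone-of-influence masking, time-localized
    and time-averaged wavelet phase coherence, the wavelet mean field and global
    coherence, intersubject surrogate thresholding with effective (surrogate
    subtracted) coherence, windowed dynamical Bayesian inference of phase
    coupling functions with directional coupling strengths and the
    percentage-time-coupled statistic, and the group-comparison machinery
    (rank-sum, Friedman, Kruskal-Wallis, Cohen's d, shuffled-segment
    repeatability, minimum-detectable-effect-size sensitivity analysis). A
    synthetic-data module generates two-mode non-autonomous test signals,
    unidirectionally coupled phase oscillators, and two-group multichannel
    cohorts with a controllable coupling deficit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
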