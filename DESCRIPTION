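Package: ambulassr
Title: Auditory Steady-State Response Analysis for Mobile EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing auditory steady-state responses (ASSR) in
    mobile EEG recorded during free walking. Implements the full analysis
    chain: rereferencing, zero-phase filtering, PCA+Infomax ICA decomposition
    with spectrum- and topography-based selection of ASSR and occipital alpha
    components, aperiodic (1/f) spectral parameterization with Gaussian peak
    extraction, gait-turn detection from gyroscope traces, time-resolved
    narrowband (Hilbert) ASSR power and a 39/41 Hz lateralization index with
    turn-locked contrasts, burst-evoked ASSR perturbation and P1/P2 ERP
    measures, cluster-based permutation tests, repeated-measures ANOVA with
    Greenhouse-Geisser correction, and robust one-sided Spearman correlations.
    A seeded synthetic-data generator produces forward-mixed EEG, gyroscope
    traces and stimulus schedules with known ground truth so that every stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ica,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
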