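Package: vibropop
Title: Population Coding and Psychophysics of Vibrotactile Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking Go/No-Go tactile
    psychophysics to layer-2/3 cortical population activity recorded with
    two-photon calcium imaging. Provides psychometric fitting and
    signal-detection metrics (detection threshold, slope, relative
    criterion), fluorescence preprocessing (neuropil correction, baseline
    estimation, dF/F, event-aligned z-scoring with first-lick masking), a
    percentile randomization test for per-trial stimulus-evoked activation
    and inhibition, ensemble statistics (pairwise cosine similarity, E/I
    ratio, single-cell and population signal-to-noise ratios), and
    frame-by-frame cross-validated logistic decoding of detection with
    shuffled-label chance estimation. A seeded synthetic cohort generator
    emulates the behavioral and imaging structure of such experiments for
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
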