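Package: lfptheta
Title: Cerebello-Hippocampal LFP Theta Coherence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing simultaneous local field
    potential (LFP) recordings from the dorsal hippocampus and cerebellar
    cortex during behaviour. Provides multitaper spectrograms and coherograms
    (discrete prolate spheroidal tapers), magnitude and imaginary coherency,
    behavioural epoching from speed, distance-from-reward coherence profiles
    with occupancy normalisation, bootstrap shuffle nulls for speed
    correlations, spike-LFP theta phase locking with Rayleigh statistics,
    optogenetic photo-identification of units, and a synthetic-session
    generator with known ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
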