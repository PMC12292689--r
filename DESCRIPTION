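Package: pianosynergy
Title: Muscle Synergy, Fatigue Monitoring and Hand Biomechanics for
    Piano-Based Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for piano-integrated upper-limb rehabilitation analysis.
    Generates synthetic multichannel surface EMG with known synergy structure
    and programmable fatigue dynamics, builds non-negative frequency x time x
    space EMG tensors via the Morlet continuous wavelet transform, extracts
    muscle synergies by non-negative CP (CP-ALS) tensor factorization and
    non-negative matrix factorization with a FIT-based synergy-count rule,
    scores rehabilitation progress as spatial/frequency/temporal synergy
    similarity against a reference model, computes a Comprehensive Muscle
    Fatigue Index (CMFI) from windowed RMS, median frequency, permutation
    entropy and fractal dimension weighted by the dominant-synergy muscle
    weights, and forward-simulates the key-finger-exoskeleton dynamics with
    Hill-type muscle torques and PD assistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
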