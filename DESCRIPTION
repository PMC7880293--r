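Package: mmnerp
Title: Mismatch Negativity Analysis for Passive Auditory Oddball EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing passive auditory oddball experiments and
    analysing the mismatch negativity (MMN) they elicit. The package builds
    exact-count oddball and same-stimulus control sequences, simulates
    continuous multi-channel EEG with parametric event-related potential
    components and 1/f background noise (including a multiplicative
    suppression of the deviance-related component, as after inhibitory rTMS
    of motor cortex), implements a standard preprocessing chain (polyphase
    resampling, mastoid re-referencing, zero-phase band-pass filtering,
    epoching with baseline correction, amplitude-based artifact rejection and
    design-based epoch exclusion), computes traditional and identity
    (same-stimulus) MMN difference waves with peak-window amplitude measures,
    and provides the statistical layer: pointwise paired t tests with a
    consecutive-timepoint (run-length) significance criterion, one-, two-
    sample and paired t tests with Cohen's d, a 2x2 mixed ANOVA with partial
    eta squared, and a Monte Carlo harness characterising the family-wise
    error of the run-length criterion. A minimal EDF reader/writer and a
    seeded end-to-end pipeline driver make runs fully reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
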