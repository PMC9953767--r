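Package: qeegnorm
Title: Normative Quantitative EEG Analysis for Double-Banana Bipolar Montages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of resting-state EEG recorded with the
    longitudinal bipolar ("double banana") montage. Reads 19-channel 10-20
    recordings (EDF or delimited text), band-pass filters and downsamples
    them, reconstructs the bipolar montage, and derives per-subject features:
    log-transformed band power areas (delta, theta, alpha, beta), Shannon
    spectral entropy, magnitude-squared coherence by band, and posterior
    dominant rhythm frequency and amplitude, grouped by frontal,
    parieto-occipital and temporal lobes and by hemisphere. Ships normative
    age-regression equations for healthy subjects, fits new normative curves
    from cohorts, derives band-structure orderings by age group, and includes
    an age-parameterized synthetic rsEEG generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    nortest,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
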