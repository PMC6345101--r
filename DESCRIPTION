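Package: gammacoh
Title: Gamma-Band EEG Power and Coherence Across Behavioral States
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying low-gamma (30-45 Hz) electroencephalogram
    power and cross-cortical coherence across behavioral states (alert and
    quiet wakefulness, NREM and REM sleep) and pharmacological conditions
    such as sub-anesthetic ketamine. Implements the Welch-block
    magnitude-squared coherence estimator with the variance-stabilizing
    z'-transform, band summaries, time-resolved coherograms, multitaper
    (Slepian) and Morlet wavelet spectrograms, gamma burst detection and
    burst-triggered averaging, a channel block-shuffle surrogate null, and
    the associated inferential layer (one-way ANOVA with Tamhane T2
    post-hoc, repeated-measures ANOVA with Bonferroni post-hoc). A
    synthetic multichannel EEG generator with known state-dependent
    cross-channel burst coupling provides ground truth for validating
    every stage, including a closed-form expected band coherence. EDF and
    CSV input/output round out an end-to-end, seed-reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, grDevices, signal, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bursts.R'
    'coherence.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'spectral.R'
    'stats.R'
    'synthetic.R'
    'utils.R'
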