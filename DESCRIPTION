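Package: hfoseeg
Title: Interictal High-Frequency Oscillation Biomarkers in Stereo-EEG
Version: 0.1.0
Authors@R: person("hfoseeg", "developers", role = c("aut", "cre"),
    email = "maintainers@hfoseeg.dev")
Description: Detects and classifies high-frequency oscillations (ripples
    80-250 Hz, fast ripples 250-600 Hz) and sharp epileptiform spikes in
    intracranial stereo-EEG using a Hilbert-envelope detector with a
    skewness-adapted threshold and a time-frequency topographic classifier
    that separates authentic oscillations from Gibbs filter ringing.
    Quantifies how per-contact event rates localize the seizure-onset zone
    (mixed-effects models, repeated-measures rate comparisons, ROC with
    bootstrap confidence intervals), measures the spatial reliability of
    rate maps across recording conditions with a scalar-product permutation
    test, and scores resection outcome with contingency metrics and exact
    binomial confidence intervals. Ships a seeded synthetic iEEG cohort
    generator with ground-truth event labels so every stage is testable
    without clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
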