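Package: ebmstager
Title: Event-Based Model Staging of Disease Progression with Neural
    Synchrony Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Robust linear z-score event-based modelling (EBM) of disease
    progression from cross-sectional biomarkers. Provides signed z-scoring
    with covariate adjustment, exhaustive quantile-grid optimization of
    event thresholds, Markov chain Monte Carlo inference over
    order-constrained event sequences, posterior staging, and
    probability-weighted metric trajectories with bootstrap stage
    comparisons under false-discovery-rate control. Also computes
    leakage-corrected amplitude-envelope correlation and relative spectral
    band power from regional electrophysiological time courses, and ships
    synthetic-cohort and synthetic-signal generators with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
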