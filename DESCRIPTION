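Package: lidquant
Title: Quantification of Levodopa-Induced Dyskinesia Progression from
    Neural and Behavioral Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for tracking the progression of
    levodopa-induced dyskinesia (LID) in parkinsonian mice across
    repeated treatment. Implements fiber-photometry preprocessing
    (isosbestic motion correction, exponential bleach normalization,
    dF/F) and envelope-based calcium-transient detection; abnormal
    involuntary movement (AIM) score metrics (windowed AUC,
    time-to-resolution, velocity binning); in vivo single-unit
    screening and levodopa-response classification (putative D1 /
    putative D2 / no-change by rank-sum test on binned firing rates);
    ex vivo intracellular feature extraction (rheobase, action
    potential threshold, half-width, AHP, mEPSC detection, GIRK
    dopamine-response ratios); and session-level statistics linking
    neural metrics to behavior. Seeded synthetic-session generators
    with known ground truth stand in for animal recordings so every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
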