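Package: slgcss
Title: Group-Constrained Subject-Specific Parcellation and Pattern
    Similarity for Auditory Statistical-Learning fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing auditory statistical-learning (SL)
    experiments in which listeners are exposed to structured (triplet-based)
    and random stimulus sequences while 3D contrast maps are acquired per
    subject. Provides constrained stimulus-sequence generation with exact
    timing, behavioural scoring of button-press logs (valid-response
    windows, log-RT contrasts, the piecewise A-prime sensitivity index,
    framewise-displacement exclusion), group-constrained subject-specific
    (GCSS) watershed parcellation of probability-of-activation maps,
    subject-level conjunction mapping, local pattern similarity analysis
    (parcel-level and whole-brain searchlight with Fisher normalization),
    and a synthetic multi-subject cohort generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
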