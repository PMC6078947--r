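Package: compdrop
Title: EEG Decoding of Retrieval Competition and Its Decline Across
    Retrieval Practice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate EEG analysis of memory-retrieval
    competition. Trains within-subject sliding-window classifiers that
    separate high- from low-competition cued recall, transfers them across
    sessions to obtain per-item competition-probability grids over
    (training time, testing time), derives a per-item competition-drop
    score across repeated retrieval-practice rounds, and tests whether
    that drop predicts delayed recall using pooled t-test grids with
    cluster-based permutation family-wise correction and a subject-level
    bootstrap. Includes signal preprocessing (zero-phase band-pass and
    notch filtering, average re-referencing, epoching with baseline
    correction, theta-band Hilbert power), classifier-weight diagnostics
    (cosine-distance representational dissimilarity matrices and the
    Haufe weight-to-pattern transform), behavioral analyses of response
    configurations, and a multi-subject synthetic-data generator with
    planted ground truth for validating every stage by parameter recovery
    and error-rate control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
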