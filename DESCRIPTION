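Package: ofstate
Title: Operator Functional State Classification from Physiological and
    Contextual Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying operator functional state (OFS) in
    supervisory-control tasks such as drone-swarm monitoring. Simulates
    operator sessions (screen events, RR-interval and pupil-diameter
    streams, subjective workload probes), derives a dynamic three-level
    task-difficulty label from target counts, message counts and the
    spatial entropy of on-screen targets, extracts per-second z-normalized
    SDNN and pupil-diameter features, trains and evaluates SVM, k-nearest
    neighbour and random-forest classifiers at a pooled (between-subject)
    and an individual (within-subject) layer, and validates labels and
    predicted states against Instantaneous Self-Assessment and Likert
    probes with Spearman and Kendall tau-b rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
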