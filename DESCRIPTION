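Package: animent
Title: Cross-Cultural Animations-Task Mentalising Analysis with Movement
    Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and Bayesian analysis of bi-directional mentalising
    in the animations (moving-triangles) task across cultures and autistic /
    non-autistic groups. Generates synthetic studies with the crossed
    generator-by-observer design (trajectories, rating sessions, ratings),
    extracts movement-kinematic features (mean jerk, observer-animation jerk
    difference, per-cell jerk variability), computes the trial accuracy
    statistic, and fits a catalogue of Bayesian crossed random-effects
    models with posterior summaries, directional posterior probabilities,
    Savage-Dickey density ratios, PSIS leave-one-out model comparison and
    posterior cell-mean contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
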