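Package: coupledraw
Title: Univariate, Coherence and Neural-Network Correlates of Bimanual
    Coupling in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating trial-by-trial bimanual coupling during
    circle-line drawing to motor-cortical EEG. Provides a synthetic session
    generator (pen trajectories plus 9-channel EEG with configurable
    univariate, distributed-linear or distributed-nonlinear encodings of the
    coupling index), curvature-based behavioural analysis, Morlet
    time-frequency log-ratio maps with event-related desynchronization and
    3600-dimensional feature vectors, Welch magnitude-squared cross-channel
    coherence, a shallow 3600-100-1 feedforward regressor trained with
    variable-learning-rate backpropagation and early stopping over repeated
    random train/validation/test splits, and correlation-based comparison of
    the three approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
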