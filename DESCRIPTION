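Package: isiwin
Title: Adaptive Estimation of Inter-Stimulus Interval Windows for
    Paired Mechanical and Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates an individual's effective inter-stimulus interval
    window (ISI-W) between peripheral mechanical stimulation and
    sub-threshold transcranial magnetic stimulation from noisy
    motor-evoked-potential (MEP) observations.  Provides four adaptive
    estimation strategies (single-Gaussian nonlinear regression, support
    vector machine regression, Gaussian process regression, and a
    particle filter) wrapped in an observe-acquire-refit loop with an
    explicit stopping rule and two-sigma window extraction; a virtual
    subject simulator with the timing model of a pneumatic tendon-tapping
    protocol; and an evaluation harness (interval-overlap F1, profile
    correlation, convergence rate, trial budgets) for benchmarking the
    estimators against incremental-sweep ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
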