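Package: nitrack
Title: Subject-Independent EEG Neural Indicator of Task Proficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a subject-independent neural indicator (NI) of
    task proficiency from multi-channel EEG recorded during repeated-trial
    training. Implements individual-alpha-frequency (IAF) relative band-power
    features via the filter-Hilbert method, baseline z-normalization, 1-s
    epoch feature tables, certainty-ranked proficiency class construction,
    minimum-redundancy maximum-relevance (mRMR) feature selection with linear
    support-vector-machine classification under leave-one-participant-out
    evaluation, the per-trial neural indicator with block trends, mixed-model
    regression, correlation analyses and permutation-null significance tests.
    Includes a synthetic cohort generator that emulates the statistical
    structure of single-session navigation-training EEG so the full pipeline
    is testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
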