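Package: loopmem
Title: Holistic Episodic Retrieval Analysis for Closed- and Open-Loop Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the behavioural and ROI-level analysis of holistic
    episodic retrieval in closed-/open-loop cued-recognition experiments.
    Generates counterbalanced factorial designs (encoding and retrieval
    schedules with null trials and adjacency constraints), simulates
    retrieval outcomes from a latent all-or-none mixture and subject-level
    ROI contrasts with a known hippocampal-neocortical coupling, computes
    the retrieval-dependency statistic against the independent contingency
    table model, runs the within-subject behavioural inference layer
    (one-sample t tests, 2x2 repeated-measures ANOVA, Bonferroni
    presentation, noncentral-t power analysis), and fits the
    hippocampal-coupling mixed model with slope/intercept contrasts across
    delay and a leave-k-out robustness procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
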