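Package: timelinr
Title: Analysis of Boundary-Segmented Timeline Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to design, simulate, and analyze serial-position timeline
    memory experiments with event-boundary segmentation under within-subject
    stimulation conditions. Provides experimental-design generation with
    counterbalancing, a generative behavioral simulator for encoding and
    timeline responses, Monte-Carlo and exact chance-level nulls for timeline
    placement error, trial exclusion and subject-cell aggregation, univariate
    repeated-measures ANOVA with partial eta squared, Bonferroni-corrected
    paired posthocs with Cohen's d, robust trimmed-mean re-analysis,
    dependent-correlation contrasts, covariate ANOVAs, exact identification
    tests, noncentral-F power analysis, and a reproducible end-to-end
    pipeline with CSV/JSON outputs and a Markdown report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
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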