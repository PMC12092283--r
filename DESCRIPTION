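Package: ddfx
Title: Difference-in-Differences Treatment Effects for Repeated-Measures
    Molecular Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for randomized two-arm trials with repeated
    molecular profiling (e.g. kidney-transplant biopsy transcriptomes at
    baseline and two follow-up visits). Derives cell-selective gene sets from
    a reference cohort and cell expression profiles, summarizes biopsies into
    gene-set activity scores, tests score-level treatment effects with
    aligned-rank-transform ANOVA, PERMANOVA omnibus tests and mixed-effects
    trajectory slopes, computes genome-wide difference-in-differences
    (delta-delta) fold-change contrasts with empirical-Bayes moderated
    t-statistics, and performs over-representation and rank-based gene-set
    enrichment. Includes a synthetic-data generator that plants known
    treatment effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    limma,
    lme4,
    lmerTest,
    permute,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
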