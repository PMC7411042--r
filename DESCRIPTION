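Package: lotkar
Title: Cohort Life-Table Demography, Euler-Lotka Growth Rates and
    Transcriptome Decontamination Filters
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cohort life-table experiments censused at fixed
    intervals: construction of survivorship (lx) and age-specific fecundity
    (mx) schedules from individual-level records, solution of the
    Euler-Lotka renewal equation for the intrinsic rate of population
    increase r with percentile-bootstrap confidence intervals, and a
    survival/fecundity statistical battery (Kaplan-Meier curves, pairwise
    log-rank tests, Kruskal-Wallis, pairwise Wilcoxon with Bonferroni
    correction, GLM fitting with AIC model selection) implemented from
    first principles. Also provides the sequence-side filters used in
    de novo transcriptome studies of laboratory cohorts: competitive contig
    assignment by bit-score gain against contaminant databases, rRNA
    flagging, and low-count gene filtering, together with synthetic
    generators for cohorts, tabular alignment hits and count matrices so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    survival,
    SummarizedExperiment,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
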