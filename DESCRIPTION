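Package: epiroa
Title: Epigenetic Clock Rate-of-Aging Analysis for Two-Arm Intervention Cohorts
Version: 0.1.0
Authors@R:
    person("epiroa", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes epigenetic ages from CpG beta-value matrices under
    linear, age-transformed, rate (pace-of-aging), and principal-component
    clock architectures; derives rate of aging (ROA, epigenetic age divided
    by chronological age) and its two-year change; and provides the
    downstream statistics used in homocysteine-lowering intervention
    analyses: threshold sweeps of per-arm regression slopes, bootstrapped
    between-group p-values, Hedges' g effect-size profiling, robust
    (Huber) regression of ROA change on cognitive scores, and partial
    correlation adjustment for baseline homocysteine. Includes a seeded
    synthetic cohort generator emulating an elderly mild-cognitive-
    impairment trial population so the full pipeline is testable without
    access to proprietary methylation data, plus a command-line workbench
    for reproducible runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
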