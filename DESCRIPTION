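Package: egfrcea
Title: Markov Cohort Cost-Effectiveness Modelling of First-Line EGFR-TKI
    Therapy in NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressive disease, death)
    Markov cohort model for health-economic evaluation of first-line
    treatments in EGFR-mutant non-small cell lung cancer. Calibrates
    per-cycle transition probabilities from digitized Kaplan-Meier curves
    via Weibull survivor functions, accrues discounted costs and
    quality-adjusted life years with regimen-level drug costing
    (per-kg, per-BSA and whole-vial billing), and computes incremental
    cost-effectiveness ratios, average cost-effectiveness ratios, net
    monetary benefit, the drug-cost reduction needed to reach a
    willingness-to-pay threshold, one-way (tornado) sensitivity analyses
    and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Ships configuration fixtures for six first-line
    EGFR-TKI trials and a synthetic digitized-curve generator with known
    ground truth.
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
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
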