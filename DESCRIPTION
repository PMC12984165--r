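Package: mammocea
Title: Cost-Effectiveness Modelling of AI-Assisted Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-cohort Markov state-transition model for early health
    technology assessment of mammography reading strategies in a national
    breast cancer screening programme for women aged 50-69. Compares
    conventional double reading against an AI companion reader and standalone
    AI interpretation, tracking cancer onset, preclinical progression,
    screen and interval detection, treatment, remission, recurrence and
    death. Produces cumulative diagnostic counts, discounted costs and
    quality-adjusted life years, incremental cost-effectiveness ratios and
    net monetary benefit, one-way deterministic sensitivity (tornado)
    tables, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves over a willingness-to-pay grid. Includes a
    synthetic natural-history generator and an individual-level
    microsimulation used to validate the cohort engine.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
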