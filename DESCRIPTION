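Package: crcscreen
Title: Cost-Effectiveness Modelling of Community-Based Colorectal Cancer
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus Markov cohort model for evaluating the
    cost-effectiveness of one-off community colorectal cancer screening
    against no screening, from the payer perspective. Implements a 15-state
    annual-cycle state-transition model with 5-year post-polypectomy tunnel
    states, half-cycle-corrected and discounted accrual of costs, life years
    and quality-adjusted life years, incremental cost-effectiveness reporting
    against a willingness-to-pay threshold, and one-way sensitivity analysis
    with tornado ordering. Also provides parameter-estimation helpers
    (five-year survival to annual transition-probability conversion,
    per-capita cost allocation, median treatment costs with outlier removal)
    and a synthetic participant-level screening-registry generator for
    testing the estimation stage without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
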