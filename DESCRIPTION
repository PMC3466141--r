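Package: matchqual
Title: Match-Quality Diagnostics and Recruitment Accounting for Matched
    Comparison Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating candidate comparison groups matched to an
    index cohort (for example cancer survivors matched to peer-nominated and
    commercially listed controls). Implements pair-level match-quality
    diagnostics based on absolute within-pair differences, rank-sum
    permutation tests valid for partially paired data (within-pair label
    swaps combined with count-preserving reassignment of unpaired
    observations), marginal-distribution permutation tests that respect the
    matched structure, deterministic recruitment-funnel yield and
    cost-per-complete accounting, and a synthetic cohort generator for
    type-I error and power simulation.
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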