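Package: dsalloc
Title: D-Optimal Allocation of Subjects to the Arms of a Parallel Study
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allocates subjects with known baseline covariates to the arms of a
    parallel intervention study by maximizing the Ds criterion, the determinant
    of the residual sums-of-squares-and-products matrix of the treatment
    contrasts after projecting out the covariates. Provides the Ds-efficiency
    measure, a seeded restart-based pairwise-exchange optimizer with a
    brute-force oracle for small instances, complete and stratified
    randomization baselines with Monte-Carlo efficiency distributions, balance
    reporting in the style of baseline tables, a synthetic covariate-table
    generator emulating a three-arm nutrition trial with 162 subjects, and a
    command-line interface.
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
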