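Package: skittler
Title: Solution-Space and Release-Timing Analysis for Virtual Throwing Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Model-based analysis of redundant throwing tasks of the virtual
    skittles (tetherball) family. Implements the closed-form damped two-spring
    ball flight, scoring of throws against a target and central post, mapping
    of the execution space (release angle by release velocity) into an error
    surface with extraction of the solution manifold, conversion of recorded
    arm trajectories into error trajectories with per-throw timing error and
    timing window, a synthetic minimum-jerk trajectory generator for
    multi-day practice cohorts, and per-session summaries with standardized
    regression of performance error on the two timing measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    grDevices,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
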