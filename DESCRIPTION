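Package: pctsim
Title: Simulation of Hierarchical Perceptual Control, Goal Conflict, and
    Reorganization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and simulating negative-feedback control
    units in the perceptual control theory (PCT) tradition: single
    closed loops with analytic steady-state companions, multi-level
    hierarchies where higher-level outputs set lower-level references,
    goal-conflict architectures, and trial-and-error (E. coli style)
    reorganization of connection strengths under sustained error.
    Includes seeded scenario runners for conflict-resolution
    experiments, psychotherapy-outcome trajectory cohorts on a CORE-10
    style scale, approach-avoidance compromise behaviour, and
    parameter fitting of control models to tracking data, all
    returning tidy tibbles with ggplot2 plotting helpers.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
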