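Package: extinctsim
Title: Extinction Events and the Evolution of Evolvability in a
    Limited-Capacity Niche Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of evolvability evolving on a toroidal
    grid of limited-capacity niches, with recurring mass-extinction events.
    Each organism carries a niche coordinate and a heritable niche-shift
    probability (its evolvability); niches hold a bounded number of
    individuals with resident priority, and extinction events spare only a
    few randomly chosen occupied niches. The package provides the simulator,
    extinction-schedule abstractions (none, fixed-interval, random-uniform),
    population and run metrics (average evolvability, niche occupancy,
    evolvability heatmaps, post-extinction rebound), self-contained
    Mann-Whitney U and Spearman rank-correlation tests, a multi-run
    experiment harness with severity sweeps, file output, plotting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
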