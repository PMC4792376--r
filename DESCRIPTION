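Package: schoolcontacts
Title: Proximity-Sensor Contact Networks for Schools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses weighted student contact networks from
    wireless proximity-sensor (mote) beacon logs. Raw beacon records are
    filtered by signal strength, aggregated into tick-level pair
    observations, segmented into encounters (maximal runs of consecutive
    ticks) and accumulated into daily cumulative contacts. From the
    resulting weighted network the package computes density, degree,
    strength, clustering, edge overlap ratios, grade and classroom contact
    matrices, time-binned degree, weighted modularity against externally
    given grade or classroom partitions with threshold sweeps, and
    power-law fits to encounter and contact duration distributions. A
    synthetic school-day generator with cohort (elementary-style) and
    individualized (high-school-style) schedules makes the whole pipeline
    testable without sensor deployments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
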