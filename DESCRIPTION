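Package: stepkymo
Title: Kymograph Analysis of Stepwise Erk Activity Border Regression in the
    Zebrafish Presomitic Mesoderm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stepwise posterior regression of the Erk (FGF)
    activity border in FRET ratio time-lapse movies of the zebrafish
    presomitic mesoderm. Builds FRET/CFP ratio movies, kymographs along a
    line of interest, extracts the activity-border trajectory by isoline
    analysis, detects step change-points with Savitzky-Golay derivatives,
    computes interval distributions and their coefficient of variation,
    tracks somite-boundary cells retrogradely, measures somite sizes from
    border plateaus, and fits the interval-size correlation. Ships a
    clock-and-wavefront simulator that generates ground-truth movies for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
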