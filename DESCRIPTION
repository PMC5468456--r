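Package: geochipr
Title: Functional Gene Biogeography from GeoChip Microarray Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for biogeographic analysis of functional
    gene microarray (GeoChip) data along environmental gradients: signal
    preprocessing (signal-to-noise filtering, replicate-singleton removal,
    total-signal normalization, log transform), alpha-diversity profiling,
    the elevation-decay relationship of Sorensen similarity with bootstrap
    inference, ubiquitous/unique gene accounting, community-environment
    linkage (Mantel tests, PERMANOVA, constrained ordination, variation
    partitioning, FDR-adjusted correlation screens), and random-matrix-theory
    thresholded co-occurrence networks.  Includes a calibrated synthetic-data
    generator with known ground truth so that every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
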