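Package: pocketcons
Title: Evolutionary Conservation and Druggability of Protein Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An open pipeline for combined evolutionary-conservation and
    druggability analysis of protein binding pockets. Grades per-column
    conservation from a multiple sequence alignment and a neighbor-joining
    tree built on BLOSUM62 distances, detects pockets on a fine grid with
    geometric burial and polarity descriptors, scores them with the published
    SiteScore and DScore equations, maps fragment-probe hotspots and ranks
    consensus clusters by nonbonded contacts, and classifies sites with a
    combined conservation-by-druggability filter. Includes generators for
    synthetic structures with engineered cavities, alignments evolved along a
    known tree with site-rate classes, and conformational ensembles, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    phangorn,
    Biostrings,
    bio3d,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
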