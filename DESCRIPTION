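Package: mousecomp
Title: Competitive-Ability Analysis for House-Mouse Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying competitive ability between wild-derived
    house-mouse (Mus musculus domesticus) populations from three data streams:
    dyadic encounter ethograms (conflict segmentation, dominance scoring,
    behavioural ordination), RFID antenna logs from two-arena enclosures
    (occupancy inference, movement metrics), and 13-locus microsatellite
    genotypes (admixture-based population assignment and likelihood-ratio
    parentage with a top-two-parent consensus rule). A self-contained kernel
    of exact and permutation statistics (binomial, rank, Friedman, ANOSIM,
    Mantel, PERMANOVA) backs every stage, and agent-based generators produce
    synthetic ethogram, enclosure and pedigree data with ground truth for
    validation.
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
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
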