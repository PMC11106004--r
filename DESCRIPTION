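Package: picocycle
Title: Seasonal Water-Column Stability and Picophytoplankton Amplicon
    Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing picoeukaryote amplicon communities across
    the annual cycle of a subtropical ocean time series. Derives mixed-layer
    depth, light-fraction depths and the deep chlorophyll maximum from CTD
    profiles, classifies water-column stability periods (deep mixing, spring
    transition, stratified summer, autumn transition) with a state machine,
    filters amplicon samples by rarefaction-curve saturation, normalizes ASV
    counts against total, plastid or prasinophyte denominators, summarises
    composition by period and vertical zone, links 16S plastid ASVs to
    18S-defined candidate species by within-genus abundance correlation, and
    categorises ASVs from ephemeral to persistent. Includes formula-level
    implementations of the rank-based statistics used (Spearman,
    Kruskal-Wallis, Dunn, ANOSIM on Hellinger-transformed abundances) and a
    synthetic-data generator that plants known ground truth so every stage is
    testable without downloading field data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
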