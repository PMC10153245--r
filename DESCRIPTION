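Package: prophagr
Title: Prophage Landscapes in Bacterial Genomes: Simulation, Detection and
    Distributional Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the prophage content of bacterial genome
    assemblies. Provides a synthetic lysogen-cohort generator that plants
    prophage cassettes with contrasting nucleotide composition into
    host-like genome backbones; a compositional prophage detector built on
    per-ORF window features (median ORF length, same-strand runs, phage
    k-mer scores, GC/AT-skew deviations) and a random-forest classifier,
    with direct-repeat (att site) boundary refinement and an evidence-based
    verification step; distributional statistics for prophage density,
    genome-size binning, kernel density modes, and Hartigans' dip test of
    unimodality with Monte-Carlo p-values; and a DNA maintenance-cost model
    for the energetic burden of carrying prophages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
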