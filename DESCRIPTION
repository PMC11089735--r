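Package: topowindow
Title: Window-Tree Discordance and Ancient Introgression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window phylogenomic analysis of gene-tree/species-tree
    discordance and ancient introgression. Classifies per-window trees into
    canonical rooted topology classes, detects runs of identical topologies
    along chromosomes, computes ABBA-BABA D-statistics with a weighted block
    jackknife, tests distance shifts in candidate regions by block permutation,
    and calls introgressed and introgression-resistant regions from percentile
    and run-length criteria. A multispecies-coalescent simulator with a single
    timed introgression pulse generates fully labelled synthetic datasets so
    every stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
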