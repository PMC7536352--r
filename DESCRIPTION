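Package: cpkit
Title: Chloroplast Genome Hybrid Assembly Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a chloroplast
    (cp) genome hybrid-assembly workflow: extraction of cp reads from
    whole-genome sequencing data by alignment rules, suffix-prefix merging
    and circularization of draft contigs, pileup consensus polishing with
    accurate short reads, inverted-repeat-aware reference-guided
    scaffolding of fragmented contigs, detection and LSC-first
    canonicalization of the quadripartite plastome structure
    (LSC/IRA/SSC/IRB), gene-annotation census, and short-branch collapsing
    for cp phylogenies.  A seeded synthetic-data module generates
    quadripartite genomes, long and short reads, and assembler-like contig
    sets so that every stage can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    stringr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
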