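Package: gmvote
Title: Genome Majority Vote for Consistent Prokaryotic Gene Start Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes predicted translation start sites among orthologous
    genes in sets of related microbial genomes using a genome majority vote.
    Builds pan-reciprocal best-hit ortholog sets from length-normalized
    pairwise protein identities, aligns upstream-extended nucleotide
    sequences, and reassigns minority start sites to caller-proposed
    alternatives that coincide with the majority start column. Includes the
    closed-form binomial error model of consensus start correction,
    projection formulas for consistency and correction rates, evaluation
    statistics against validated gene starts, and a synthetic-genome
    generator for end-to-end parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
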