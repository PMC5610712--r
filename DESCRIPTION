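Package: panforge
Title: Bacterial Pan-Genome Inference from Ortholog Families, Rarefaction and
    Whole-Genome Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A comparative pan-genomics toolkit for bacterial strain panels.
    Infers ortholog gene families from reciprocal best hits followed by
    two-stage clustering (single linkage then Markov clustering), builds the
    augmented presence/absence matrix, and characterises the pan-genome by
    permutation rarefaction of core, pan and new-gene counts with a Heaps-law
    openness test. Computes whole-genome average nucleotide identity (ANI) and
    percentage of conserved proteins (POCP) with threshold classification and
    complete-linkage clustering of the resulting matrices, builds concatenated
    core-gene alignments with gap-column stripping, SNP distances and
    bootstrapped neighbour-joining trees, assigns contigs to replicon classes
    via marker genes and reference homology, and profiles functional gene
    content per replicon. Includes a synthetic multi-replicon genome-panel
    generator with known family structure so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    ape,
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
    igraph,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
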