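Package: gcdrift
Title: GC-Content Dynamics Around Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary dynamics of GC-content
    around transcription start sites (TSSs) of protein-coding genes:
    metagene GC, per-nucleotide and CpG profiling on positional and
    binned (mRNA 20-bin, TSS/EIB 41-bin, ORF 40-bin) coordinate schemes;
    outgroup-parsimony inference of lineage-assigned nucleotide
    substitutions from aligned sequence trios; net weak-to-strong /
    strong-to-weak substitution series; de novo mutation mapping with CpG
    context classification; fourfold-degenerate (GC4) site analysis;
    Wilcoxon signed-rank and label-shuffling permutation statistics; and
    a synthetic genome / trio-evolution simulator (AT-biased mutation,
    CpG hypermutability, optional GC-biased gene conversion near
    anchors) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    rtracklayer,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
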