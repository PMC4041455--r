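Package: osseq
Title: Oligonucleotide-Selective Sequencing Probe Design, Capture QC and
    Breakpoint Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted capture assays in which immobilized 101-mer
    primer probes select genomic regions directly on the sequencing flow cell.
    Builds k-mer mapability tracks with mismatch-margin uniqueness, designs
    primer probes for exons, contiguous loci, SNPs and putative structural
    variant breakpoints under GC, uniqueness, SNP-overlap and repeat-adjacency
    constraints, assembles full-length oligos, demultiplexes and classifies
    captured reads via the probe sequence carried in Read 2, computes per-probe
    yield, capture rate, one-log uniformity and region-of-interest coverage,
    calls allele fractions with fixed thresholds, and resolves exact structural
    variant breakpoints by probe-grouped read filtering, local de Bruijn
    assembly and split-alignment contig validation. A deterministic simulator
    generates synthetic genomes, implanted variants, mixtures and
    capture-chemistry read pairs so the whole stack is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
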