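Package: congener
Title: Guided Genome Assembly and Comparative Analysis of Congeneric Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A toolkit for building and comparing genomes of closely related
    (congeneric) species against an established reference assembly. Implements
    reference-assisted assembly primitives (insert-size modelling, mate-pair
    filtering, 30-mer contig bridging, bounded k-mer gap filling, scaffold
    reordering and assembly merging), anchor-based scaffold-to-chromosome
    placement with AGP output, assembly statistics, a 20 kb inter-chromosomal
    rearrangement rule, reciprocal-best-hit ortholog dot plots, pileup-based
    single-nucleotide-change and InDel calling with effect classification and
    summarisation, and transposable-element age landscapes based on Kimura
    two-parameter distances. A synthetic-data module generates reference plus
    diverged congener genome pairs with planted truth (point mutations, InDels,
    translocations, TE insertions) and tiered paired-end libraries, so every
    analysis is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
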