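Package: diplopair
Title: Haplotype-Pair Detection and Divergence Analysis for
    Hyper-Heterozygous Diploid Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing genome assemblies in which the two
    haplotypes of a highly heterozygous diploid assemble as separate
    scaffolds, as seen in parthenogenetic nematodes.  Detects allelic
    scaffold pairs by seeded self-alignment with reciprocal-best
    one-to-one tiling, quantifies heterozygosity (SNV and indel
    densities, per-annotation-class rates, 100-bp window tracks,
    inversion and translocation calls), classifies ortholog groups into
    allelic pairs, singletons and gene families with a diploid
    gene-number estimator, compares allele-specific expression by FPKM
    fold change, computes codon-aware CDS divergence and
    counting-method dN/dS, clusters 3'-EST tags by greedy identity
    thresholding, and estimates genome size from a two-component k-mer
    spectrum mixture.  A synthetic diploid-genome simulator with
    complete truth ledgers makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
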