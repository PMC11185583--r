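Package: sdpoly
Title: Population Analysis of Segmental Duplication Polymorphism from
    Haplotype Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects segmental duplications (blocks of homologous DNA longer
    than 1 kbp with at least 90 percent sequence identity) in haplotype
    genome assemblies, projects them onto a reference genome to build a
    pangenome frequency map of fixed, polymorphic and private duplications,
    characterizes their orientation and dispersion, genotypes duplicated-gene
    copy number both from assemblies and from GC-corrected read depth, tests
    for population-differentiated copy number, and screens long-read
    transcripts for reference-divergent paralogs. Includes a synthetic cohort
    generator with planted duplication events and machine-readable truth
    tables so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
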