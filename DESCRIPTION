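Package: viranet
Title: Comparative Genomics of Metabolite-Network Protein Domains in Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for surveying protein
    domain families across collections of viral genomes. Provides taxid-based
    proteome de-duplication, iterative position-specific profile searches with
    empirically calibrated E-values, single-linkage sequence clustering by
    bit-score density, conserved gene-neighborhood mining with an inter-gene
    distance cutoff, contextual-absence queries, and genome-size-stratified
    prevalence, enrichment and co-occurrence statistics. Includes a synthetic
    viral-genome generator with planted ground truth (size-dependent domain
    carriage, morphology bias, conserved neighborhoods, co-occurrence) so the
    whole pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
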