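Package: celtag
Title: CRISPR Knock-In Tagging Designs and Tagged-Allele Survey Statistics
    for C. elegans
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide design of SpCas9 knock-in reagents for endogenous
    protein tagging in Caenorhabditis elegans: maturation-aware N- and
    C-terminal insertion sites inferred from curated protein-processing
    features, NGG guide enumeration and filtering in windows around each
    insertion point, Hamming-distance off-target counting, and
    homology-arm/genotyping primer design with synonymous (silent)
    mutations that protect the repair template from re-cutting. Also
    implements the statistics used to survey the community's tagged-allele
    inventory: curation and deduplication rules, summary distributions,
    linear and exponential-saturation accrual models, and category
    enrichment with capped log2 odds ratios, Fisher's exact test and
    Benjamini-Hochberg FDR. A deterministic synthetic-fixture generator
    provides genomes, gene models, feature tables and inventories with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
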