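Package: diffscan
Title: Genome Scans for Islands of Differentiation Between Hybridizing
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate genomic islands of differentiation between two
    hybridizing populations from bi-allelic SNP genotypes. Implements per-SNP
    Weir-Cockerham F_ST and fixed/shared/exclusive polymorphism classification,
    sliding-window scans with Z-scores and Fisher exact tests of the
    fixed-to-shared ratio, threshold-and-merge island demarcation, relative
    node depth (RND) and site-frequency-spectrum statistics (Watterson's
    theta, pi, Tajima's D, Fay and Wu's H) per target fragment, positional
    enrichment tests (sex chromosome, centromere proximity), a permutation
    test of genomic clustering, and a structured-coalescent simulator for a
    two-deme isolation-with-migration model providing a neutral null
    distribution for the fixed-to-shared polymorphism ratio. A synthetic-data
    generator produces complete two-population test genomes with background
    gene flow, planted low-introgression islands and an outgroup.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
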