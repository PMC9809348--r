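Package: breedmark
Title: Breed-Specific Variant Discovery and Population Structure for Multi-Breed Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies breed-specific single-nucleotide polymorphisms in
    multi-breed diploid genotype panels using a per-population allele
    frequency criterion (both alleles tested, strict 0.9 threshold by
    default, with configurable background exclusions for related
    populations), together with the supporting pipeline: minor allele
    frequency and exact Hardy-Weinberg equilibrium quality control, codon
    level synonymous/nonsynonymous consequence annotation from FASTA and
    GFF3 gene models, GRM-based principal component analysis and
    neighbor-joining trees from p-distances for verifying population
    distinctness, gene-set over-representation (hypergeometric and EASE),
    per-chromosome descriptive reports, and a synthetic multi-breed data
    generator (Balding-Nichols drift with planted breed-private alleles)
    that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
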