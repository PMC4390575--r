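Package: inbredvar
Title: Genotype Quality Control and Population Genomics for Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for panels of sequenced inbred lines sampled
    from multiple populations. Detects blocks of residual heterozygosity in
    nominally inbred genomes by two-state segmentation, applies class-wise
    genotype-quality filters (different rules for SNPs and indels, and for
    heterozygous calls inside versus outside het blocks), validates calls
    against deep-coverage read-count ratios, scans for identity-by-descent
    segments within populations, genotypes large chromosomal inversions from
    breakpoint-spanning read evidence and quantifies their association with
    het blocks, polarizes alleles against outgroups, and computes unfolded
    site frequency spectra, windowed diversity statistics (pi, Watterson's
    theta, Tajima's D, polymorphism/divergence), Hudson's F_ST and LD decay.
    Includes a synthetic-cohort simulator (island-model differentiation,
    planted inversions and het blocks, quality-stratified genotype errors,
    read counts, diverged outgroups) with full ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    withr
Config/testthat/edition: 3
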