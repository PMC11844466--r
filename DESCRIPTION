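Package: haplokit
Title: Haplotype-Resolved Variant and Allele Analysis for Duplicated
    Immunoglobulin Constant Loci
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing an immunoglobulin heavy-chain constant
    (IGHC) style locus from haplotype-resolved long-read assemblies: a
    synthetic-locus simulator with machine-readable truth (planted SNVs,
    structural variants, gene alleles, tiled reads), a k-mer anchored
    contig-to-reference aligner with coordinate liftover, assembly
    benchmarking (windowed error rates, per-base read support, phase-switch
    counts, diploid genotype concordance), assembly- and read-based SNV
    calling with SV masking, structural-variant detection and genotyping from
    alignment chains, copy-number-aware region-haplotype clustering, allele
    extraction and novel-allele naming with read-support validation, and
    population statistics (Weir-Cockerham FST, PCA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
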