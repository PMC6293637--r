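Package: lcgeno
Title: Genotype Calling from Low-Coverage Sequencing Without Reference-Allele Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for calling genotypes from low-coverage whole-genome
    sequencing data while avoiding bias towards the reference allele. Extracts
    allele read counts for known biallelic SNP sites directly from aligned
    reads (BAM), bypassing the pruned read counts stored in gVCF files by
    graph-based variant callers; computes genotype probabilities from the
    counts and calls genotypes at several certainty levels; evaluates calls
    with coverage-stratified genotype and allele concordance tables; emulates
    the reference-allele bias introduced by read-threading-graph pruning at
    low coverage; quantifies alignment bias with a tailored (allele-swapped)
    reference genome and REF/ALT/CIS/TRANS count combinations; and simulates
    and estimates index hopping in multiplexed libraries by inverse regression
    of concordance percentages and their isometric log-ratio transforms. A
    synthetic-data generator produces truth genotypes, reads and standard
    BAM/VCF/FASTA/TSV fixtures so every analysis is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
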