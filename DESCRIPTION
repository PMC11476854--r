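Package: autozyg
Title: Runs of Homozygosity, Genomic Inbreeding and Proband-Unique Variant
    Analysis for Pedigreed Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from multi-sample VCF
    genotypes with a sliding-window scanner, estimates the genomic
    inbreeding coefficient F_ROH as the autosomal ROH fraction, and
    compares it with pedigree-expected inbreeding computed by the
    recursive kinship (tabular) method, including closed-form
    expectations for full-sib matings with inbred founders.  Implements
    GATK-style hard filtering of SNVs (QD, FS, MQ, SOR, rank-sum
    statistics and a depth-percentile rule), known-variant exclusion,
    proband-unique variant selection in trio/quartet designs, ROH-gene
    interval overlap with keyword triage of enrichment tables, and a
    seeded gene-dropping simulator (founder haplotype pools, Haldane
    crossovers) that generates pedigree-structured genotype data with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
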