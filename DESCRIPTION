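Package: eqtlexplorer
Title: Cis-eQTL Mapping, Linkage Disequilibrium and Post-GWAS Variant Exploration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis expression quantitative trait loci (cis-eQTLs) for
    biallelic SNPs and indels across multiple populations using a five-model
    minimum-P association statistic (additive, dominant, recessive, genotypic
    2-df and dominance-deviation tests), computes pairwise linkage
    disequilibrium (r-squared and D-prime) from phased haplotypes or by EM
    haplotype-frequency estimation from unphased genotypes, builds an
    LD-preserving permutation null by shuffling expression phenotypes,
    classifies variants into genomic categories relative to gene models and
    tests enrichment of real versus permuted cis-eQTLs, and intersects a GWAS
    catalog with the cis-eQTL database to discover high-LD indel taggers of
    GWAS SNPs. Includes a seeded synthetic-data generator (multi-population
    phased genotypes with LD blocks, planted cis effects and planted taggers)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
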