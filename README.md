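# eqtlexplorer

Cis-eQTL mapping, linkage disequilibrium and post-GWAS variant exploration
for SNPs **and indels**.

Most GWAS hits land in non-coding sequence, and the variant a genotyping
array reports is rarely the functional one. Two workhorse analyses connect
an association signal to a mechanism: expression quantitative trait locus
(eQTL) mapping, which asks whether a variant's genotype correlates with a
gene's expression, and linkage disequilibrium (LD) analysis, which finds
the proxies that travel on the same haplotypes as the reported SNP.
Indels — the second most abundant variant class in the human genome, and
often more disruptive than SNPs — are usually invisible to both, because
arrays do not type them. `eqtlexplorer` implements the full post-GWAS
exploration loop with indels as first-class citizens, for analysts working
with population-scale phased genotypes (e.g. 1000 Genomes-style panels)
and expression matrices.

## What it computes

**Five-model minimum-P cis-eQTL statistic.** For each variant–probe pair
inside the cis window (±200 kb of the gene by default) and each
population, five classical quantitative-trait models are fitted by
ordinary least squares on the alt-allele dosage *g* ∈ {0, 1, 2}:

| model | design | test |
|---|---|---|
| ADD | *y* ~ *g* | t, df = n − 2 |
| DOM | *y* ~ 1[*g* ≥ 1] | t, df = n − 2 |
| REC | *y* ~ 1[*g* = 2] | t, df = n − 2 |
| GENO_2DF | *y* ~ *g* + het | F, df = (2, n − 3) |
| DOMDEV | *y* ~ *g* + het | t on het, df = n − 3 |

with het = 1[*g* = 1]. The cis-eQTL score is the smallest p-value across
the estimable models (**min-P**); the relaxed database cutoff is
min-P < 10⁻², the strict distribution-analysis cutoff 10⁻⁴. Pairs passing
in ≥2 populations are *population-shared*, in exactly one
*population-specific*, and per (probe, population, variant class) the
smallest-min-P record is the *peak* eQTL.

**LD engine.** r² and D′ from phased haplotype counting, or from unphased
genotypes via EM haplotype-frequency estimation (double-heterozygote phase
resolved iteratively from a linkage-equilibrium start). Proxy search
reports all variants with r² ≥ 0.7 to a query inside a 1000 kb window.

**LD-preserving permutation null.** Expression sample labels are shuffled
jointly across probes; genotypes — and therefore every LD relationship —
stay untouched. Pooled "fake cis-eQTLs" from repeated permutations are the
null reference for genomic-region enrichment (±10 kb TSS, 3′UTR, exon,
ncRNA, intron, intergenic; 2×2 chi-squared real vs. fake).

**GWAS explorer.** Intersects a GWAS catalog with the eQTL database,
reports catalog coverage and the eSNP fraction, finds indel cis-eQTLs
tagging eSNPs at r² ≥ 0.7 (and in perfect LD, r² = 1), and assembles
per-query reports that prioritize proxies which are simultaneously
cis-eQTLs and regulatory-region overlaps — exportable as a UCSC custom
track (BED9).

**Synthetic studies.** A seeded generator builds the whole input set —
multi-population phased VCF with LD blocks, indels planted in perfect or
calibrated partial LD with SNPs, expression with cis effects planted under
any of ADD/DOM/REC, gene models (BED12), regulatory BED, toy GWAS catalog
— plus a ground-truth manifest, so every stage is testable end to end.

## Worked example

```r
library(eqtlexplorer)

man   <- demo_manifest(seed = 1)           # 6 populations x 80 samples
gm    <- simulate_haplotypes(man)          # phased genotype matrix
em    <- simulate_expression(gm, man)      # 20 planted cis effects
genes <- gene_model(man$genes, man$exons)

rec <- classify_sharing(
  cis_scan_all(gm, em, genes, man$panel, cutoff = 1e-4))
sharing_summary(rec)$by_class
#>   vclass n_pairs n_shared shared_pct
#> 1  INDEL      19       11       57.9
#> 2    SNP     145       60       41.4

ci <- catalog_intersect(man$catalog, rec, gm$variants$vid, cutoff = 1e-2)
ci
#> GWAS catalog intersection:
#>   40 / 43 catalog SNPs in panel (93.0%)
#>   20 / 40 present SNPs are cis-eQTLs (50.00%) for 14 genes
#>   8 / 8 traits with >= 1 eSNP (100.00%)

find_indel_taggers(ci$esnps, rec, gm, man$panel)
#> indel taggers: 20 eSNPs queried; 12 tagged at high LD (60.0%), 5 in perfect LD (25.0%)
```

The sharing table partitions the variant–probe pairs that pass the strict
cutoff into population-shared and population-specific fractions per
variant class; the catalog intersection reports how many toy GWAS SNPs are
genotyped and how many are eSNPs; the tagger summary counts eSNPs whose
signal an indel cis-eQTL can stand in for. The five planted perfect
taggers are all found at r² = 1. A single LD computation looks like:

```r
a <- c(rep(1, 50), rep(0, 50)); b <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
ld_phased(a, b)
#> ld_result [phased]: r2 = 0.36, D' = 0.6 (n_hap = 100)
```

## Command line

```sh
Rscript inst/cli/eqtl-explorer.R simulate --seed 1 --out fixtures/
Rscript inst/cli/eqtl-explorer.R eqtl-scan --vcf fixtures/genotypes.vcf \
  --panel fixtures/panel.tsv --expression fixtures/expression.tsv \
  --probe-map fixtures/probe_map.tsv --genes fixtures/genes.bed \
  --cutoff 1e-4 --out records.tsv
Rscript inst/cli/eqtl-explorer.R tag-gwas --vcf fixtures/genotypes.vcf \
  --panel fixtures/panel.tsv --expression fixtures/expression.tsv \
  --probe-map fixtures/probe_map.tsv --genes fixtures/genes.bed \
  --catalog fixtures/gwas_catalog.tsv --out taggers.tsv
```

Subcommands: `simulate`, `eqtl-scan`, `permute`, `ld`, `annotate`,
`enrich`, `tag-gwas`, `explore`, `export-track`. Logs go to stderr,
results to files/stdout; invalid thresholds, missing inputs and unknown
subcommands exit with distinct nonzero codes.

## Scope notes

The package reimplements the analysis engine natively; it does not bundle
reference datasets (1000 Genomes genotypes, expression archives, the NHGRI
catalog, Ensembl regulatory builds) — users supply their own VCF, TSV and
BED snapshots. Genotype imputation, microarray normalization, multiallelic
record splitting and trans-eQTL analysis are out of scope.
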