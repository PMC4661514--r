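---
title: "Methods: five-model cis-eQTL mapping, LD and the permutation null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five-model cis-eQTL mapping, LD and the permutation null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlexplorer)
```

This vignette is the package's account of its statistical machinery: the
association models and their assumptions, the LD estimators, the
permutation null, the genomic-region classifier, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The five-model minimum-P statistic

A cis-eQTL here is a **variant–probe pair**: expression is measured per
transcript probe and one gene may carry several probes, so probe-level
records are the primitive and gene-level views are derived. For each pair
and population we regress expression $y$ on recodings of the alt-allele
dosage $g \in \{0,1,2\}$:

* **ADD** — $y = \beta_0 + \beta_1 g$, two-sided t-test on $\beta_1$,
  $n-2$ df. Equivalent to the Pearson-correlation t-test (an identity the
  test suite asserts to $10^{-10}$).
* **DOM** — predictor $1[g \ge 1]$; **REC** — predictor $1[g = 2]$; same
  simple-regression t-test.
* **GENO_2DF** — $y = \beta_0 + \beta_1 g + \beta_2\,\mathrm{het}$ with
  $\mathrm{het} = 1[g=1]$: a reparameterization of the saturated
  three-genotype-mean model; joint F-test of $\beta_1=\beta_2=0$ with
  $(2, n-3)$ df.
* **DOMDEV** — the t-test on $\beta_2$ in that same joint fit: the
  deviation of the heterozygote mean from additivity, $n-3$ df.

The eQTL score is the minimum p-value over the estimable models. This
captures effects that any single inheritance model would miss (a purely
recessive signal is nearly invisible to ADD at low allele frequency)
at the cost of an inflated per-pair type-I rate — bounded between
$\alpha$ and $5\alpha$ since the five tests are positively correlated but
not identical. That inflation is deliberately **not** corrected
analytically: the permutation module measures it empirically, and the test
suite verifies the $[\alpha, 5\alpha]$ band by simulation.

Assumptions: expression is treated as continuous with Gaussian errors
within genotype classes; fits use ordinary least squares; missing
genotype or expression values are removed pairwise per pair (maximizing
$n$, at the cost of slightly different sample sets across pairs). An
optional inverse-normal transform is not applied by default — raw values
are scanned, and the invariance tests (shift/scale of $y$) document that
p-values do not depend on the expression scale.

Degenerate designs return `NA` rather than a fabricated p-value: a
constant predictor after recoding (e.g. REC with no alt homozygotes) for
the simple models, and a rank-deficient $(g, \mathrm{het})$ design —
detected via the centered cross-product determinant at relative tolerance
$10^{-9}$ — for GENO_2DF/DOMDEV (no heterozygotes, or only two genotype
classes present). A pair whose five models are all `NA` is flagged
inestimable and excluded. Exact ties in min-P resolve by the fixed order
ADD, GENO_2DF, DOMDEV, DOM, REC, so outputs are reproducible; the case
where only dosages 0 and 2 occur (ADD, DOM and REC become affine recodes
of one predictor, hence identical p) lands on ADD.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window` | 200 000 | bp | cis window each side of the gene span |
| `cutoff` | 10⁻² | p | database cutoff (GWAS intersection) |
| strict cutoff | 10⁻⁴ | p | distribution/enrichment analyses |
| `maf_min` | 0.01 | fraction | eQTL-panel MAF filter (0.001 for LD panels) |
| `miss_max` | 0.2 | fraction | per-variant missing-rate filter (exclusive) |
| `tss_flank` | 10 000 | bp | TSS-proximal region half-width |
| `ld window` | 1 000 000 | bp | proxy-search total span |
| `r2_min` | 0.7 | r² | high-LD tagger threshold (1.0 = perfect) |
| `n_perm` | 100 | count | permutations for the null pool |
| `min_samples` | 10 | count | floor on shared samples per scan |

Sharing is evaluated at the cutoff of the table being summarized: 10⁻⁴
for the distribution analyses, 10⁻² for the GWAS intersection.

The **cis-window anchor** is genuinely ambiguous ("±window of the gene"
can mean the span or the TSS); the default anchors to the gene span,
`anchor = "tss"` selects the alternative, and the window is a closed
interval — a variant exactly at `gene_start − window` is in. Similarly
the **proxy window** phrase "a 1000 kb window" is read as the total span
(±500 kb around the query); `half_window = FALSE` reads it as ±1000 kb.

## LD estimation

With haplotype frequencies $p_{AB}, p_{Ab}, p_{aB}, p_{ab}$ and marginals
$p_A, p_B$:

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
  D' = \frac{|D|}{D_{\max}}$$

where $D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D>0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ for $D<0$; $D'$ is reported as its
absolute value in $[0,1]$ (the sign is recoverable from $D$). Phased input
is counted directly — $r^2$ then equals the squared Pearson correlation
of the binary haplotype vectors exactly. The worked four-frequency table
$(0.4, 0.1, 0.1, 0.4)$ gives $D = 0.15$, $r^2 = 0.36$, $D' = 0.6$ by
closed form.

Unphased genotypes go through an EM on the haplotype-frequency
likelihood: every two-locus genotype determines its two haplotypes except
the double heterozygote, whose cis/trans split is iterated from a
linkage-equilibrium start until the largest frequency change falls below
`tol = 1e-8` (or 1000 iterations; non-convergence is flagged, and a
sample consisting solely of double heterozygotes has two symmetric optima
and is flagged ambiguous). Phased counting is always preferred when phase
is available; EM is the fallback for unphased panels.

How close is EM to phased counting? EM estimates agree with the
composite-LD (dosage-correlation) benchmark to ~0.002 on average, i.e.
the estimator itself is sound; the residual gap to phased counting is the
information lost with phase and grows as LD weakens. In the regime the
proxy engine actually operates in — pairs at $r^2 \gtrsim 0.7$, samples
of $n = 200$, MAF ≥ 0.05 — the mean absolute $r^2$ gap is about 0.006
(the acceptance suite asserts < 0.01). At $r^2 < 0.3$ the mean gap
roughly triples; conclusions about *weak* LD from unphased data should
not lean on a 0.01 accuracy assumption.

## The permutation null

The null keeps genotypes fixed and shuffles expression **sample labels
once per permutation, jointly across all probes**. Two things are
preserved exactly: every LD relationship between variants (the genotype
matrix is untouched — the suite checks byte identity), and the
correlation structure among probes. Only the genotype–phenotype link is
broken. An alternative reading — shuffling each probe independently — is
available (`per_probe = TRUE`) but is a weaker null, since it also
destroys inter-probe correlation; the joint shuffle is the default
because enrichment comparisons should not be able to exploit expression
covariance that exists identically in the real data.

For the fake-eQTL pool, each permutation reruns the full scan and each
**variant** keeps its best record across probes (`reduce = "variant"`),
mirroring how the null pool assigns the smallest five-model p-value per
variant; `reduce = "pair"` keeps all passing pairs and is what the
calibration tests use, since the $[\alpha, 5\alpha]$ band is a per-test
statement. Permutation $k$ under base seed $s$ uses substream seed
$s + k$, so runs are reproducible and extendable.

## Genomic-region classification and enrichment

Each variant position receives exactly one of six categories by
precedence: **TSS10K** (within ±10 kb of any TSS, strand-aware signed
distance to the nearest TSS) → **UTR3** (exonic in a coding gene, 3′ of
the CDS end respecting strand) → **EXON** (coding-gene exonic otherwise;
5′UTR folds in here, since the six-way scheme has no 5′UTR slice) →
**NCRNA** (exonic in a non-coding-biotype gene) → **INTRON** (inside a
gene span, not exonic) → **INTERGENIC**. TSS-proximity outranks the
structural categories because the TSS-centric enrichment is the headline
comparison and the categories must partition; the precedence vector is an
argument for users who disagree. Classification uses the variant's
anchor position; regulatory-interval overlap, by contrast, spans an
indel's full reference allele (POS through POS + len(ref) − 1), so a
30 kb deletion overlaps features anywhere in its span.

Enrichment of real vs. fake cis-eQTLs per category is a 2×2 chi-squared
without continuity correction (genome-wide pools are large-count; Yates
is available by flag), with a `small_expected` flag when any expected
cell is below 5. MAF comparisons between sharing classes use Student's
t-test (pooled variance by default, Welch optional). Per-population
indel/SNP ratio comparisons between the specific and shared subsections
use a **paired** t-test — the same populations contribute both ratios —
with the degenerate all-zero-difference case defined as $t = 0, p = 1$.

## What the generator emulates — and what it does not

`sim_manifest()` fixes the study design; all randomness flows from one
seed, and the manifest plus seed fully determine every emitted file.

* **Haplotypes** are drawn per population at manifest frequencies;
  LD blocks use copy-with-mutation: each block variant copies the
  previous column and flips alleles with the probability that hits the
  target adjacent-pair $r^2$ (0.8 by default) in expectation, solved from
  the closed form $r^2(\varepsilon)$ by root finding. Perfect taggers
  copy a source SNP's column under indel alleles (realized $r^2$ exactly
  1); partial taggers flip toward a target (±0.1 verified at the default
  sizes). Infeasible targets error out by name.
* **Population structure** is a per-variant frequency perturbation
  (SD 0.05) around a shared base frequency — enough to make sharing
  labels and per-population MAFs meaningful.
* **Expression** is Gaussian noise (SD 1) plus planted effects
  $\beta \cdot \mathrm{encode}(g, \mathrm{model})$ for samples of the
  planting's populations.
* **Defaults** are the acceptance study: six populations × 80
  individuals, 2 000 variants (10% indels) over 8.2 Mb, 40 genes / 100
  probes, 20 planted effects at $\beta = 1.5$, five perfect and three
  partial taggers. Recessive plantings are restricted to variants with
  per-population alt frequency ≥ 0.40 and to at least two populations: a
  recessive contrast needs enough minor homozygotes ($n p^2 \approx 13$
  at $p = 0.4, n = 80$) to be estimable at all — this is a property of
  recessive genetics at this sample size, not a tuning knob.

Not emulated: recombination-gradient LD decay (blocks are exchangeable
chains, not coalescent genealogies), allele-frequency spectra skewed
toward rare variants, expression heteroskedasticity, batch effects,
population admixture, and genotyping error. Passing the recovery tests
therefore demonstrates that the pipeline is *correct on its own terms*
— effects planted under the model are found, labeled and tagged — not
that real LCL data would yield any particular eQTL count.

## Numerical choices and problem sizes

* Closed-form OLS (centered cross-products) rather than repeated `lm()`
  calls: the scan and the permutation null fit five models for up to
  hundreds of thousands of pairs; residual sums of squares are clamped at
  zero against cancellation, and perfect fits report $p$ via an infinite
  t statistic rather than dividing by zero.
* Coordinates are 1-based closed internally; BED conversions happen only
  at I/O boundaries (via rtracklayer). Indels sit at their VCF anchor
  position. Multiallelic records are skipped, not split — splitting
  changes allele frequencies and the analysis is defined for biallelic
  variants. Half-calls are conservatively missing.
* Peak-eQTL ties break by smaller genomic position; proxy lists order by
  descending $r^2$ with the query pinned first.
* The test and acceptance suites run at deliberately desk-sized scales:
  the full six-population demo (≈ 60 000 model fits) for recovery, a
  single-population 250-variant × 50-probe layout × enough permutations
  for ≥ 10⁵ (script: 2 × 10⁵) permuted tests for null calibration, and
  500 simulated pairs for the EM oracle. These sizes were chosen as the
  smallest at which the binomial/Poisson envelopes of the asserted bands
  are comfortably narrow.

## Known limitations

* The min-P statistic is reported raw; cross-gene multiple-testing
  control (e.g. FDR across probes) is intentionally out of scope — the
  two fixed cutoffs with a permutation-calibrated null follow the
  database-building design.
* EM LD from unphased genotypes assumes random mating within the sample
  (haplotypes pair independently); strong inbreeding or structure within
  a "population" slice biases it.
* The region classifier resolves overlapping genes by precedence and
  nearest TSS, so a variant intronic in one gene and exonic in another is
  counted once, by the higher-precedence category.
* `cis_scan` is single-threaded R; genome-scale inputs (10⁶ pairs × 6
  populations) are feasible but hours-long — the intended scale is
  targeted regions, simulations and method evaluation.
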