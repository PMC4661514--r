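# Shared fixtures, built once per test run. `fx` is a small two-population
# study with planted effects and taggers; all randomness is seeded through
# the manifest, so every test sees identical data.

fx <- local({
  man <- sim_manifest(
    seed = 11L,
    populations = c(CHB = 40L, YRI = 40L),
    n_variants = 400L, n_genes = 12L, n_probes = 30L,
    region_length = 3e6L, n_eqtl = 6L,
    n_taggers = 2L, n_partial_taggers = 1L)
  gm <- simulate_haplotypes(man)
  em <- simulate_expression(gm, man)
  genes <- gene_model(man$genes, man$exons)
  list(man = man, gm = gm, em = em, genes = genes)
})

# deterministic toy gene model used by region-annotation tests:
# plus-strand coding gene, minus-strand coding gene, one ncRNA
toy_genes <- function() {
  tab <- data.frame(
    gene = c("GPLUS", "GMINUS", "GNC"),
    chrom = "1", strand = c("+", "-", "+"),
    start = c(100000L, 300000L, 500000L),
    end = c(140000L, 340000L, 520000L),
    cds_start = c(100500L, 300500L, NA),
    cds_end = c(139500L, 339500L, NA),
    biotype = c("coding", "coding", "ncRNA"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene = c("GPLUS", "GPLUS", "GPLUS", "GMINUS", "GMINUS", "GNC"),
    start = c(100000L, 120000L, 139000L, 300000L, 339000L, 500000L),
    end = c(101000L, 121000L, 140000L, 301000L, 340000L, 520000L),
    stringsAsFactors = FALSE)
  gene_model(tab, exons)
}

toy_variants <- function(pos, chrom = "1", ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             vid = sprintf("v%03d", seq_along(pos)),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# build a phased genotype_matrix directly from a haplotype matrix
gm_from_haps <- function(hap, pos = NULL, ref = NULL, alt = NULL) {
  nv <- nrow(hap)
  v <- data.frame(
    chrom = "1", pos = if (is.null(pos)) seq_len(nv) * 1000L else pos,
    vid = sprintf("hv%03d", seq_len(nv)),
    ref = if (is.null(ref)) rep("A", nv) else ref,
    alt = if (is.null(alt)) rep("G", nv) else alt,
    stringsAsFactors = FALSE)
  codes <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), 2), drop = FALSE]
  genotype_matrix(v, sprintf("S%03d", seq_len(ncol(hap) / 2)), codes,
                  phased = TRUE, haplotypes = hap)
}

# haplotype pair with exact joint counts (n_AB, n_Ab, n_aB, n_ab)
haps_with_counts <- function(nAB, nAb, naB, nab) {
  a <- c(rep(1, nAB), rep(1, nAb), rep(0, naB), rep(0, nab))
  b <- c(rep(1, nAB), rep(0, nAb), rep(1, naB), rep(0, nab))
  list(a = a, b = b)
}
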