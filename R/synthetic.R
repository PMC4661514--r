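# Seeded synthetic-data generator. Emulates the study design the package
# targets: phased multi-population genotypes with block LD structure, a
# mixture of SNPs and indels (including indels planted in perfect or
# calibrated partial LD with SNPs), and probe-level expression with cis
# effects planted under any of the five genetic models. Every random draw
# flows from the manifest seed, so a manifest fully determines all outputs.

#' Build a simulation manifest
#'
#' The manifest is the ground truth: variant layout (LD blocks, indels,
#' planted taggers), per-population allele frequencies, gene/probe layout,
#' planted cis-eQTLs, regulatory intervals and a toy GWAS catalog.
#'
#' LD blocks use a copy-with-mutation construction: each block variant
#' copies the previous variant's haplotype column and flips alleles with a
#' probability calibrated so adjacent pairs hit `block_r2` in expectation.
#' Perfect taggers copy a source SNP's column under indel alleles
#' (realized r2 exactly 1); partial taggers flip toward `partial_r2`.
#'
#' @param seed Integer seed driving every downstream draw.
#' @param populations Named integer vector of population sizes.
#' @param n_variants Background variants (before taggers are appended).
#' @param n_genes,n_probes Gene and probe counts (probes are assigned to
#'   genes round-robin).
#' @param region_length Chromosome span in bp.
#' @param block_size Variants per LD block.
#' @param block_r2 Target adjacent-pair r2 inside a block.
#' @param indel_frac Fraction of background variants written as indels.
#' @param n_eqtl Planted cis effects.
#' @param eqtl_beta Effect size per planted effect (expression units per
#'   coded unit).
#' @param eqtl_sd Expression noise standard deviation.
#' @param eqtl_models Models to cycle through for plantings.
#' @param n_taggers Perfect (r2 = 1) indel taggers of planted eQTL SNPs.
#' @param n_partial_taggers Calibrated partial-LD indel taggers.
#' @param partial_r2 Target r2 for partial taggers.
#' @param maf_range Background allele-frequency range.
#' @param pop_fst Per-population frequency perturbation SD.
#' @return A list of class `sim_manifest`.
#' @export
sim_manifest <- function(seed = 1L,
                         populations = c(CEU = 80L, CHB = 80L, JPT = 80L,
                                         LWK = 80L, MEX = 80L, YRI = 80L),
                         n_variants = 2000L, n_genes = 40L, n_probes = 100L,
                         region_length = 8200000L, block_size = 10L,
                         block_r2 = 0.8, indel_frac = 0.10,
                         n_eqtl = 20L, eqtl_beta = 1.5, eqtl_sd = 1,
                         eqtl_models = c("ADD", "DOM", "REC"),
                         n_taggers = 5L, n_partial_taggers = 3L,
                         partial_r2 = 0.8,
                         maf_range = c(0.10, 0.50), pop_fst = 0.05) {
  stopifnot(all(populations >= 2), n_probes >= n_genes,
            is_count(n_variants), n_eqtl <= n_probes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  pops <- names(populations)

  # gene and probe layout: evenly spaced 10 kb genes, alternating strand,
  # two exons, CDS inside; every fifth gene is ncRNA
  spacing <- floor((region_length - 300000L) / n_genes)
  gstart <- as.integer(150000L + (seq_len(n_genes) - 1L) * spacing)
  gend <- gstart + 9999L
  strand <- rep(c("+", "-"), length.out = n_genes)
  biotype <- ifelse(seq_len(n_genes) %% 5L == 0L, "ncRNA", "coding")
  genes <- data.frame(
    gene = sprintf("GENE%03d", seq_len(n_genes)), chrom = "1",
    strand = strand, start = gstart, end = gend,
    cds_start = ifelse(biotype == "coding", gstart + 2500L, NA_integer_),
    cds_end = ifelse(biotype == "coding", gend - 2500L, NA_integer_),
    biotype = biotype, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) data.frame(
    gene = genes$gene[i],
    start = c(gstart[i], gstart[i] + 6000L),
    end = c(gstart[i] + 3999L, gend[i]), stringsAsFactors = FALSE)))
  probes <- data.frame(
    probe = sprintf("PROBE%04d", seq_len(n_probes)),
    gene = genes$gene[rep_len(seq_len(n_genes), n_probes)],
    stringsAsFactors = FALSE)

  # background variants in LD blocks
  pos <- sort(sample.int(region_length, n_variants))
  block <- rep(seq_len(ceiling(n_variants / block_size)),
               each = block_size)[seq_len(n_variants)]
  role <- ifelse(duplicated(block), "block_chain", "block_head")
  is_indel <- runif(n_variants) < indel_frac
  ref <- ifelse(is_indel, "AT", "A")
  alt <- ifelse(is_indel, "A", "G")
  variants <- data.frame(
    chrom = "1", pos = pos, vid = sprintf("rs%06d", seq_len(n_variants)),
    ref = ref, alt = alt, role = role, block = block,
    source = NA_character_, epsilon = NA_real_, stringsAsFactors = FALSE)

  # per-population head frequencies; chain frequencies follow analytically
  base <- runif(n_variants, maf_range[1], maf_range[2])
  freq <- vapply(pops, function(p)
    pmin(pmax(base + rnorm(n_variants, 0, pop_fst), 0.05), 0.95),
    numeric(n_variants))
  rownames(freq) <- variants$vid
  eps_chain <- numeric(n_variants)
  for (i in seq_len(n_variants)) {
    if (role[i] == "block_chain") {
      for (p in pops) {
        e <- flip_for_r2(freq[i - 1, p], block_r2)
        freq[i, p] <- freq[i - 1, p] * (1 - e) + (1 - freq[i - 1, p]) * e
        if (p == pops[1]) eps_chain[i] <- e
      }
      variants$source[i] <- variants$vid[i - 1]
    }
  }
  variants$epsilon <- ifelse(role == "block_chain", eps_chain, NA_real_)

  # planted cis effects: common SNPs inside the cis window of a probe's
  # gene. Recessive plantings are restricted to the commonest alleles and
  # at least two populations, since a recessive signal needs enough minor
  # homozygotes to be estimable at the per-population sample size.
  stopifnot(all(eqtl_models %in% c("ADD", "DOM", "REC")))
  min_freq <- apply(freq, 1, min)
  elig <- which(!is_indel & min_freq >= 0.25)
  plant_probe <- sample(probes$probe, n_eqtl)
  plantings <- do.call(rbind, lapply(seq_len(n_eqtl), function(k) {
    pg <- probes$gene[probes$probe == plant_probe[k]]
    gi <- match(pg, genes$gene)
    model <- eqtl_models[1 + (k - 1) %% length(eqtl_models)]
    in_win <- elig[pos[elig] >= gstart[gi] - 150000 &
                     pos[elig] <= gend[gi] + 150000]
    ok <- if (model == "REC") in_win[min_freq[in_win] >= 0.40] else in_win
    if (length(ok) == 0 && length(in_win) > 0)
      ok <- in_win[which.max(min_freq[in_win])]
    if (length(ok) == 0) ok <- elig[which.min(
      pmax(gstart[gi] - pos[elig], pos[elig] - gend[gi], 0))]
    v <- ok[sample.int(length(ok), 1)]
    elig <<- setdiff(elig, v)
    hi <- min(4L, length(pops))
    n_in <- if (model == "REC") sample(seq(min(2L, hi), hi), 1)
            else sample(seq_len(hi), 1)
    data.frame(vid = variants$vid[v], probe = plant_probe[k], gene = pg,
               model = model, beta = eqtl_beta, sd = eqtl_sd,
               populations = paste(sort(sample(pops, n_in)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(plantings))
    plantings <- data.frame(vid = character(0), probe = character(0),
                            gene = character(0), model = character(0),
                            beta = numeric(0), sd = numeric(0),
                            populations = character(0))

  # planted indel taggers of planted (eQTL) SNPs
  n_tag <- n_taggers + n_partial_taggers
  src <- plantings$vid[seq_len(min(n_tag, nrow(plantings)))]
  tag_rows <- lapply(seq_along(src), function(k) {
    si <- match(src[k], variants$vid)
    perfect <- k <= n_taggers
    e <- if (perfect) 0 else flip_for_r2(freq[si, pops[1]], partial_r2)
    data.frame(
      chrom = "1", pos = variants$pos[si] + 1L,
      vid = sprintf("rs9%05d", k), ref = "ACGT", alt = "A",
      role = if (perfect) "tagger_perfect" else "tagger_partial",
      block = NA_integer_, source = src[k], epsilon = e,
      stringsAsFactors = FALSE)
  })
  taggers <- do.call(rbind, tag_rows)
  if (!is.null(taggers)) {
    tf <- freq[match(taggers$source, variants$vid), , drop = FALSE]
    chain <- taggers$role == "tagger_partial"
    tf[chain, ] <- tf[chain, ] * (1 - taggers$epsilon[chain]) +
      (1 - tf[chain, ]) * taggers$epsilon[chain]
    rownames(tf) <- taggers$vid
    freq <- rbind(freq, tf)
    variants <- rbind(variants, taggers)
  }
  ord <- order(variants$pos)
  variants <- variants[ord, ]; freq <- freq[ord, , drop = FALSE]

  # regulatory intervals over the taggers plus decoys
  tag_pos <- variants$pos[grepl("^tagger", variants$role)]
  reg <- data.frame(
    chrom = "1",
    start = c(tag_pos - 50L, sort(sample.int(region_length - 1000L, 10L))),
    stringsAsFactors = FALSE)
  reg$end <- reg$start + 100L
  reg$feature <- sprintf("ENSR%05d", seq_len(nrow(reg)))

  # toy GWAS catalog: planted eSNPs + panel non-eQTLs + absent rsIDs
  extra <- setdiff(variants$vid[variants$ref == "A" & variants$alt == "G"],
                   plantings$vid)
  catalog <- data.frame(
    rsid = c(plantings$vid, sample(extra, min(20L, length(extra))),
             sprintf("rs8%05d", 1:3)),
    stringsAsFactors = FALSE)
  catalog$trait <- sprintf("trait_%02d", rep_len(1:8, nrow(catalog)))

  panel <- data.frame(
    sample = unlist(lapply(pops, function(p)
      sprintf("%s%03d", p, seq_len(populations[[p]])))),
    population = rep(pops, populations), stringsAsFactors = FALSE)

  structure(list(seed = as.integer(seed), populations = populations,
                 panel = panel, variants = variants, freq = freq,
                 genes = genes, exons = exons, probes = probes,
                 plantings = plantings, block_r2 = block_r2,
                 partial_r2 = partial_r2, regulatory = reg,
                 catalog = catalog, eqtl_sd = eqtl_sd),
            class = "sim_manifest")
}

#' Demo manifest at the default study scale
#'
#' Six populations of 80 individuals, 2,000 background variants in LD
#' blocks, 100 probes over 40 genes, 20 planted cis effects at beta = 1.5
#' (noise SD 1) and planted perfect/partial indel taggers.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_manifest()].
#' @return A `sim_manifest`.
#' @export
demo_manifest <- function(seed = 1L, ...) sim_manifest(seed = seed, ...)

# flip probability achieving an expected pairwise r2 of `target` when a
# haplotype column of frequency p is copied with symmetric mutation
flip_for_r2 <- function(p, target) {
  if (target >= 1 || target <= 0)
    stop2("target r2 %g infeasible: need 0 < r2 < 1 for copy-with-mutation",
          target)
  r2_of <- function(e) {
    q <- p * (1 - e) + (1 - p) * e
    (p * (1 - p) * (1 - 2 * e))^2 / (p * (1 - p) * q * (1 - q))
  }
  uniroot(function(e) r2_of(e) - target, c(1e-9, 0.5 - 1e-9))$root
}

#' Simulate phased haplotypes from a manifest
#'
#' Draws per-population haplotypes: block heads are Bernoulli draws at the
#' manifest frequency, chain variants copy the previous column with the
#' calibrated flip probability, perfect taggers copy their source column
#' exactly and partial taggers copy with flips.
#'
#' @param manifest A [sim_manifest()].
#' @return A phased [genotype_matrix()] over all populations (samples
#'   ordered as in `manifest$panel`).
#' @export
simulate_haplotypes <- function(manifest) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(manifest$seed + 1L)
  v <- manifest$variants
  nv <- nrow(v)
  pops <- names(manifest$populations)
  hap_cols <- list()
  for (p in pops) {
    nh <- 2L * manifest$populations[[p]]
    H <- matrix(0L, nv, nh)
    for (i in seq_len(nv)) {
      if (v$role[i] == "block_head") {
        H[i, ] <- rbinom(nh, 1L, manifest$freq[v$vid[i], p])
      } else {
        si <- match(v$source[i], v$vid)
        h <- H[si, ]
        e <- v$epsilon[i]
        if (e > 0) {
          flip <- runif(nh) < e
          h[flip] <- 1L - h[flip]
        }
        H[i, ] <- h
      }
    }
    hap_cols[[p]] <- H
  }
  hap <- do.call(cbind, hap_cols)
  samples <- manifest$panel$sample
  codes <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), 2), drop = FALSE]
  vt <- v[, c("chrom", "pos", "vid", "ref", "alt")]
  rownames(vt) <- NULL
  genotype_matrix(vt, samples, codes, phased = TRUE, haplotypes = hap)
}

#' Simulate expression with planted cis effects
#'
#' Each probe is Gaussian noise; planted probes additionally receive
#' `beta * encode(g, model)` for samples of the planting's populations.
#'
#' @param gm Genotype matrix from [simulate_haplotypes()].
#' @param manifest The same [sim_manifest()].
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(gm, manifest) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(manifest$seed + 2L)
  probes <- manifest$probes
  samples <- gm$samples
  vals <- matrix(rnorm(nrow(probes) * length(samples), 0, manifest$eqtl_sd),
                 nrow(probes), length(samples),
                 dimnames = list(probes$probe, samples))
  pl <- manifest$plantings
  for (k in seq_len(nrow(pl))) {
    if (!pl$probe[k] %in% probes$probe || is.na(pl$gene[k]))
      stop2("planted probe %s has no gene assignment", pl$probe[k])
    g <- gm$codes[match(pl$vid[k], gm$variants$vid), ]
    in_pop <- manifest$panel$population %in%
      strsplit(pl$populations[k], ",")[[1]]
    x <- encode_genotype(g, pl$model[k])
    vals[pl$probe[k], in_pop] <- vals[pl$probe[k], in_pop] +
      pl$beta[k] * x[in_pop]
  }
  expression_matrix(vals, setNames(probes$gene, probes$probe))
}

#' Write a complete fixture set to disk
#'
#' Emits every input the pipeline consumes: phased VCF, sample panel TSV,
#' expression TSV, probe map TSV, gene BED12, regulatory BED, GWAS catalog
#' TSV and the manifest as JSON.
#'
#' @param manifest A [sim_manifest()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_fixture_set <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- simulate_haplotypes(manifest)
  em <- simulate_expression(gm, manifest)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    panel = file.path(dir, "panel.tsv"),
    expression = file.path(dir, "expression.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    genes = file.path(dir, "genes.bed"),
    regulatory = file.path(dir, "regulatory.bed"),
    catalog = file.path(dir, "gwas_catalog.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_vcf(gm, paths$vcf)
  write.table(manifest$panel, paths$panel, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expr <- data.frame(probe = rownames(em$values), em$values,
                     check.names = FALSE)
  write.table(expr, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(manifest$probes, paths$probe_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_genes_bed12(manifest$genes, manifest$exons, paths$genes)
  reg <- manifest$regulatory
  writeLines(paste(reg$chrom, reg$start - 1L, reg$end, reg$feature,
                   sep = "\t"), paths$regulatory)
  write.table(manifest$catalog, paths$catalog, sep = "\t", quote = FALSE,
              row.names = FALSE)
  man <- manifest
  man$freq <- NULL  # bulky; reproducible from the seed
  jsonlite::write_json(unclass(man), paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  paths
}

write_genes_bed12 <- function(genes, exons, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exons$gene == g$gene, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    thick <- if (g$biotype == "coding") c(g$cds_start - 1L, g$cds_end)
             else c(g$start - 1L, g$start - 1L)
    paste(g$chrom, g$start - 1L, g$end, g$gene, 0L, g$strand,
          thick[1], thick[2], "0", nrow(ex),
          paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
          paste0(paste(ex$start - g$start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
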