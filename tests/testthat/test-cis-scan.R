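test_that("the cis window is a closed interval around the gene span", {
  genes <- gene_model(
    data.frame(gene = "G1", chrom = "1", strand = "+",
               start = 1000000L, end = 1010000L, cds_start = 1001000L,
               cds_end = 1009000L, biotype = "coding",
               stringsAsFactors = FALSE),
    data.frame(gene = "G1", start = 1000000L, end = 1010000L,
               stringsAsFactors = FALSE))
  v <- toy_variants(c(795000L, 800000L, 1210000L, 1210001L))
  pairs <- cis_pairs(genes, v, window = 200000L)
  expect_false("v001" %in% pairs$vid)  # 5 kb outside the lower boundary
  expect_true("v002" %in% pairs$vid)   # exactly on the boundary
  expect_true("v003" %in% pairs$vid)   # exactly on the upper boundary
  expect_false("v004" %in% pairs$vid)
})

test_that("cis pair enumeration matches a brute-force interval scan", {
  set.seed(301)
  genes <- gene_model(
    data.frame(gene = "G1", chrom = "1", strand = "+", start = 500000L,
               end = 510000L, cds_start = 501000L, cds_end = 509000L,
               biotype = "coding", stringsAsFactors = FALSE),
    data.frame(gene = "G1", start = 500000L, end = 510000L,
               stringsAsFactors = FALSE))
  v <- toy_variants(sort(sample.int(1000000L, 100L)))
  pairs <- cis_pairs(genes, v, window = 200000L)
  brute <- sum(v$pos >= 500000L - 200000L & v$pos <= 510000L + 200000L)
  expect_equal(nrow(pairs), brute)
  # probe expansion multiplies by probes per gene
  p2g <- c(P1 = "G1", P2 = "G1")
  pairs2 <- cis_pairs(genes, v, window = 200000L, probe2gene = p2g)
  expect_equal(nrow(pairs2), 2L * brute)
})

test_that("mismatched chromosome naming is an explicit error", {
  genes <- gene_model(
    data.frame(gene = "G1", chrom = "chr1", strand = "+", start = 1000L,
               end = 2000L, cds_start = 1100L, cds_end = 1900L,
               biotype = "coding", stringsAsFactors = FALSE),
    data.frame(gene = "G1", start = 1000L, end = 2000L,
               stringsAsFactors = FALSE))
  expect_error(cis_pairs(genes, toy_variants(1500L)), "chromosome")
})

make_planted_gm <- function(seed, n = 80L, maf = 0.3, pos = 505000L) {
  set.seed(seed)
  hap <- matrix(rbinom(2L * n, 1, maf), 1, 2L * n)
  gm_from_haps(hap, pos = pos)
}

scan_genes <- gene_model(
  data.frame(gene = "G1", chrom = "1", strand = "+", start = 500000L,
             end = 510000L, cds_start = 501000L, cds_end = 509000L,
             biotype = "coding", stringsAsFactors = FALSE),
  data.frame(gene = "G1", start = 500000L, end = 510000L,
             stringsAsFactors = FALSE))

test_that("a planted additive effect is recovered at the strict cutoff", {
  hits <- 0L
  for (rep in 1:40) {
    gm <- make_planted_gm(400 + rep)
    set.seed(4000 + rep)
    y <- 1.5 * gm$codes[1, ] + rnorm(80)
    em <- expression_matrix(matrix(y, 1, 80,
                                   dimnames = list("P1", gm$samples)),
                            c(P1 = "G1"))
    rec <- cis_scan(gm, em, scan_genes, cutoff = 1e-4)
    if (nrow(rec) == 1 && rec$min_p < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # >= 95% recovery
})

test_that("an effect outside the cis window is never reported", {
  gm <- make_planted_gm(499, pos = 810000L)  # 300 kb past the gene end
  set.seed(4999)
  y <- 1.5 * gm$codes[1, ] + rnorm(80)
  em <- expression_matrix(matrix(y, 1, 80,
                                 dimnames = list("P1", gm$samples)),
                          c(P1 = "G1"))
  rec <- cis_scan(gm, em, scan_genes, cutoff = 1)
  expect_equal(nrow(rec), 0L)
})

test_that("a null scan stays inside the Bonferroni binomial envelope", {
  set.seed(305)
  n <- 60L; n_var <- 100L; n_probe <- 50L  # 5000 pairs
  hap <- matrix(rbinom(n_var * 2L * n, 1, runif(n_var, 0.15, 0.5)),
                n_var, 2L * n)
  gm <- gm_from_haps(hap, pos = 500000L + seq_len(n_var) * 50L)
  vals <- matrix(rnorm(n_probe * n), n_probe, n,
                 dimnames = list(sprintf("P%02d", 1:n_probe), gm$samples))
  em <- expression_matrix(vals, setNames(rep("G1", n_probe),
                                         rownames(vals)))
  rec <- cis_scan(gm, em, scan_genes, cutoff = 1e-4)
  upper <- qbinom(0.995, 5000L, 5 * 1e-4)
  expect_lte(nrow(rec), upper)
})

test_that("records respect the window and the strict/relaxed flag nesting", {
  rec <- cis_scan_all(fx$gm, fx$em, fx$genes, fx$man$panel, cutoff = 1e-2)
  gt <- fx$genes$table
  gi <- match(rec$gene, gt$gene)
  lo <- pmin(gt$start[gi], gt$end[gi]) - 200000L
  hi <- pmax(gt$start[gi], gt$end[gi]) + 200000L
  expect_true(all(rec$pos >= lo & rec$pos <= hi))
  expect_true(all(rec$passes_relaxed))
  expect_true(all(rec$passes_strict == (rec$min_p < 1e-4)))
  expect_true(all(!rec$passes_strict | rec$passes_relaxed))
})

test_that("sharing classification matches population membership", {
  rec <- data.frame(
    vid = c("v1", "v1", "v2", "v3", "v3", "v3"),
    probe = "P1", vclass = "SNP", pos = 1L, chrom = "1",
    population = c("CHB", "JPT", "YRI", "CHB", "JPT", "YRI"),
    min_p = 1e-5, stringsAsFactors = FALSE)
  out <- classify_sharing(rec)
  expect_equal(out$sharing[out$vid == "v1"], rep("shared", 2))
  expect_equal(out$sharing[out$vid == "v2"], "specific")
  expect_equal(unique(out$populations[out$vid == "v3"]), "CHB,JPT,YRI")
})

test_that("sharing labels of recovered plantings match the manifest", {
  rec <- classify_sharing(
    cis_scan_all(fx$gm, fx$em, fx$genes, fx$man$panel, cutoff = 1e-4))
  pl <- fx$man$plantings
  for (k in seq_len(nrow(pl))) {
    pops <- strsplit(pl$populations[k], ",")[[1]]
    sub <- rec[rec$vid == pl$vid[k] & rec$probe == pl$probe[k] &
                 rec$population %in% pops, ]
    if (nrow(sub) == 0) next
    truth <- if (length(pops) >= 2) "shared" else "specific"
    if (nrow(sub) == length(pops))  # fully recovered
      expect_equal(unique(sub$sharing), truth)
  }
})

test_that("peak reduction takes the argmin per probe/population/class", {
  rec <- data.frame(
    vid = sprintf("v%d", 1:5), chrom = "1", pos = c(10L, 20L, 30L, 40L, 50L),
    vclass = c("SNP", "SNP", "SNP", "INDEL", "INDEL"),
    probe = "P1", population = "CHB",
    min_p = c(1e-5, 1e-7, 1e-6, 1e-3, 1e-3), stringsAsFactors = FALSE)
  out <- peak_reduce(rec)
  expect_equal(out$vid[out$is_peak], c("v2", "v4"))  # one peak per class,
  # indel tie broken by position
  expect_identical(peak_reduce(out)$is_peak, out$is_peak)  # idempotent
})

test_that("peak flags equal a brute-force argmin on a random table", {
  set.seed(306)
  rec <- data.frame(
    vid = sprintf("v%03d", 1:300), chrom = "1",
    pos = sample.int(1e6, 300),
    vclass = sample(c("SNP", "INDEL"), 300, TRUE),
    probe = sample(sprintf("P%d", 1:10), 300, TRUE),
    population = sample(c("CHB", "YRI"), 300, TRUE),
    min_p = 10^-runif(300, 1, 8), stringsAsFactors = FALSE)
  out <- peak_reduce(rec)
  key <- paste(rec$probe, rec$population, rec$vclass)
  for (k in unique(key)) {
    idx <- which(key == k)
    best <- idx[order(rec$min_p[idx], rec$pos[idx])][1]
    expect_true(out$is_peak[best])
    expect_equal(sum(out$is_peak[idx]), 1L)
  }
  expect_false(any(out$min_p[out$is_peak] >
                     tapply(rec$min_p, key, min)[key][out$is_peak]))
})

test_that("sharing summary arithmetic reproduces printed-style percentages", {
  # counts at the scale of a genome-wide table: 21,841 indel pairs of which
  # 4,976 shared; 228,743 SNP pairs of which 53,926 shared
  mk <- function(n, n_shared, vclass, prefix) {
    shared_pairs <- data.frame(
      vid = sprintf("%s_s%06d", prefix, seq_len(n_shared)), probe = "P1",
      vclass = vclass, population = "CHB", min_p = 1e-5,
      stringsAsFactors = FALSE)
    shared2 <- shared_pairs; shared2$population <- "JPT"
    spec <- data.frame(
      vid = sprintf("%s_x%06d", prefix, seq_len(n - n_shared)), probe = "P1",
      vclass = vclass, population = "CHB", min_p = 1e-5,
      stringsAsFactors = FALSE)
    rbind(shared_pairs, shared2, spec)
  }
  rec <- rbind(mk(21841L, 4976L, "INDEL", "i"),
               mk(228743L, 53926L, "SNP", "s"))
  s <- sharing_summary(classify_sharing(rec))
  expect_equal(s$by_class$shared_pct[s$by_class$vclass == "INDEL"], 22.8)
  expect_equal(s$by_class$shared_pct[s$by_class$vclass == "SNP"], 23.6)
})

test_that("indel/SNP ratios and percentage complements behave", {
  rec <- data.frame(
    vid = c(sprintf("i%02d", 1:10), sprintf("s%03d", 1:100)),
    probe = "P1", vclass = c(rep("INDEL", 10), rep("SNP", 100)),
    chrom = "1", pos = 1L,
    population = "CHB", min_p = 1e-5, stringsAsFactors = FALSE)
  s <- sharing_summary(classify_sharing(rec))
  bp <- s$by_population
  expect_equal(bp$indel_snp_ratio_specific, 0.100)
  expect_equal(bp$shared_pct + bp$specific_pct, 100)
  # detection-rate monotonicity across planted effect sizes
  set.seed(307)
  rates <- vapply(c(0.25, 0.5, 1.0), function(beta) {
    hit <- 0L
    for (rep in 1:20) {
      gm <- make_planted_gm(700 + rep * 13 + round(beta * 100))
      y <- beta * gm$codes[1, ] + rnorm(80)
      em <- expression_matrix(matrix(y, 1, 80,
                                     dimnames = list("P1", gm$samples)),
                              c(P1 = "G1"))
      rec <- cis_scan(gm, em, scan_genes, cutoff = 1e-4)
      if (nrow(rec) > 0) hit <- hit + 1L
    }
    hit / 20
  }, 1)
  expect_true(all(diff(rates) >= 0))
})
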