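test_that("region classification follows the documented precedence", {
  genes <- toy_genes()
  v <- toy_variants(c(
    95000,    # 5 kb upstream of GPLUS TSS -> TSS10K, distance -5000
    100500,   # exonic but within the TSS flank -> TSS10K wins
    115000,   # inside GPLUS, not exonic, 15 kb from TSS -> INTRON
    120500,   # exonic, inside CDS, > 10 kb from TSS -> EXON
    139800,   # exonic, past the CDS end on + strand -> UTR3
    2000000,  # 1 Mb+ from any gene -> INTERGENIC
    515000,   # exonic in the ncRNA gene, beyond the TSS flank -> NCRNA
    300200))  # exonic past CDS start on - strand (3' end) -> UTR3
  ann <- classify_region(v, genes)
  expect_equal(ann$category,
               c("TSS10K", "TSS10K", "INTRON", "EXON", "UTR3",
                 "INTERGENIC", "NCRNA", "UTR3"))
  expect_equal(ann$tss_distance[1], -5000)
  expect_equal(ann$anchor_gene[1], "GPLUS")
  expect_true(is.na(ann$tss_distance[6]))
})

test_that("tss distance is strand-aware and negates on strand flip", {
  genes <- toy_genes()
  v <- toy_variants(c(95000, 103000))
  d_plus <- classify_region(v, genes)$tss_distance
  flipped <- genes
  flipped$table$strand[flipped$table$gene == "GPLUS"] <- "-"
  flipped$table$tss[flipped$table$gene == "GPLUS"] <- 100000L  # same coord
  d_minus <- classify_region(v, flipped)$tss_distance
  expect_equal(d_minus, -d_plus)
  # minus-strand gene: downstream coordinates are negative distances
  ann <- classify_region(toy_variants(345000), genes)
  expect_equal(ann$anchor_gene, "GMINUS")
  expect_equal(ann$tss_distance, -5000)  # 5 kb past the - strand TSS
})

test_that("category assignment partitions any variant set", {
  set.seed(501)
  v <- toy_variants(sort(sample.int(2500000L, 400L)))
  ann <- classify_region(v, toy_genes())
  expect_false(any(is.na(ann$category)))
  cnt <- region_counts(ann)
  expect_equal(sum(cnt), 400L)
  expect_true(all(ann$category %in% names(cnt)))
})

test_that("the 2x2 enrichment chi-squared matches a textbook computation", {
  # identical proportions: no signal
  same <- enrichment_test(c(TSS10K = 90), c(TSS10K = 90), "TSS10K",
                          real_total = 1000, fake_total = 1000)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  res <- enrichment_test(c(TSS10K = 90), c(TSS10K = 50), "TSS10K",
                         real_total = 1000, fake_total = 1000)
  # independent textbook oracle: chi2 = sum (O - E)^2 / E over the 2x2
  O <- matrix(c(90, 910, 50, 950), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2_or <- sum((O - E)^2 / E)
  expect_equal(res$chi2, chi2_or, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chi2_or, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_error(enrichment_test(c(TSS10K = 0), c(TSS10K = 5), "TSS10K",
                               real_total = 0, fake_total = 100),
               "totals")
})

test_that("small expected cells are flagged, not fatal", {
  res <- enrichment_test(c(NCRNA = 2), c(NCRNA = 1), "NCRNA",
                         real_total = 30, fake_total = 30)
  expect_true(res$small_expected)
  expect_true(is.finite(res$chi2))
})

test_that("enrichment p-values are uniform for same-distribution pools", {
  set.seed(502)
  ps <- replicate(100, {
    a <- rbinom(1, 1000, 0.1); b <- rbinom(1, 1000, 0.1)
    enrichment_test(c(TSS10K = a), c(TSS10K = b), "TSS10K",
                    real_total = 1000, fake_total = 1000)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("MAF group comparison behaves like a Student t-test", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  same <- maf_compare(x, x)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_true(is.na(maf_compare(rep(0.2, 5), rep(0.2, 5))$p))
  expect_error(maf_compare(0.1, c(0.1, 0.2)), "n >= 2")

  set.seed(503)
  hits <- replicate(20, {
    g1 <- rnorm(200, 0.3, 0.05); g2 <- rnorm(200, 0.2, 0.05)
    maf_compare(g1, g2)$p < 1e-4
  })
  expect_gte(mean(hits), 0.99)
})

test_that("per-population ratio comparison uses a paired t-test", {
  r1 <- c(CHB = 0.094, JPT = 0.096, CEU = 0.097, YRI = 0.098,
          LWK = 0.099, MEX = 0.100)
  same <- ratio_compare(r1, r1)
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  r2 <- r1 - c(0.004, 0.007, 0.005, 0.006, 0.008, 0.006)
  res <- ratio_compare(r1, r2)
  d <- r1 - r2
  t_or <- mean(d) / (sd(d) / sqrt(length(d)))
  p_or <- 2 * pt(-abs(t_or), length(d) - 1)
  expect_equal(res$t, t_or, tolerance = 1e-12)
  expect_equal(res$p, p_or, tolerance = 1e-12)

  expect_error(ratio_compare(r1, r2[1:5]), "same populations")
  expect_error(ratio_compare(0.1, 0.2), "at least 2")
})

test_that("regulatory overlap converts BED coordinates and spans indels", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t99\t100\tfA",    # 1-based base 100 only
               "1\t98\t99\tfB",     # base 99 only
               "1\t100\t101\tfC",   # base 101 only
               "1\t150\t200\tfD"), bed)
  reg <- load_regulatory_bed(bed)
  v <- data.frame(chrom = "1", pos = c(100L, 100L), vid = c("snp", "del"),
                  ref = c("A", strrep("A", 30000)), alt = c("G", "A"),
                  stringsAsFactors = FALSE)
  ov <- regulatory_overlap(v, reg)
  expect_equal(ov$snp, "fA")
  # the 30 kb deletion spans bases 100..30099 and catches everything right
  expect_true(all(c("fA", "fC", "fD") %in% ov$del))
  expect_false("fB" %in% ov$del)
})

test_that("interval overlap matches a brute-force double loop", {
  set.seed(504)
  v <- toy_variants(sample.int(100000L, 1000L))
  v$ref <- sample(c("A", "ATTT"), 1000L, TRUE)
  starts <- sort(sample.int(99000L, 50L))
  reg <- GenomicRanges::GRanges("1", IRanges::IRanges(starts + 1L,
                                                      starts + 500L))
  S4Vectors::mcols(reg)$feature <- sprintf("f%02d", 1:50)
  ov <- regulatory_overlap(v, reg)
  for (i in seq_len(nrow(v))) {
    span <- c(v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L)
    brute <- sprintf("f%02d", which(starts + 1L <= span[2] &
                                      starts + 500L >= span[1]))
    expect_equal(sort(ov[[v$vid[i]]]), sort(brute))
  }
})

test_that("malformed BED input is rejected with a file error", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("1\t100", "oops"), bad)
  expect_error(load_regulatory_bed(bad), "malformed BED")
})
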