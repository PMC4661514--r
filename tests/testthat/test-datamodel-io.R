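test_that("variant classification separates SNPs from indels", {
  expect_equal(classify_variant("A", "G"), "SNP")
  expect_equal(classify_variant("A", "AT"), "INDEL")
  expect_equal(classify_variant("ATG", "A"), "INDEL")
  expect_equal(classify_variant(c("A", "AT"), c("C", "A")),
               c("SNP", "INDEL"))
  expect_error(classify_variant("A", "G,T"), "multiallelic")
  expect_error(classify_variant("A", "A"), "differ")
  expect_error(classify_variant("", "A"), "nonempty")
})

write_mini_vcf <- function(path, gts, pos = 100L, ref = "A", alt = "T",
                           id = "rs1", extra_lines = character(0)) {
  samples <- sprintf("S%d", seq_along(gts))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("1", pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t"),
    extra_lines), path)
  path
}

test_that("a phased VCF record loads as dosages 0/1/2 with phase", {
  path <- write_mini_vcf(tempfile(fileext = ".vcf"),
                         c("0|0", "0|1", "1|1"))
  gm <- load_vcf(path, maf_min = 0)
  expect_equal(unname(gm$codes[1, ]), c(0L, 1L, 2L))
  expect_true(gm$phased)
  expect_equal(unname(gm$haplotypes[1, ]), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(gm$variants$vclass, "SNP")
})

test_that("the MAF filter is a folded boundary on the selected samples", {
  # alt frequency 3/6 = 0.5: kept at maf_min 0.4
  p1 <- write_mini_vcf(tempfile(fileext = ".vcf"), c("0|0", "0|1", "1|1"))
  expect_equal(nrow(load_vcf(p1, maf_min = 0.4)$variants), 1L)
  # alt frequency 1/6: dropped at maf_min 0.2
  p2 <- write_mini_vcf(tempfile(fileext = ".vcf"), c("0|0", "0|1", "0|0"))
  expect_warning(gm2 <- load_vcf(p2, maf_min = 0.2), "no variants pass")
  expect_equal(nrow(gm2$variants), 0L)
})

test_that("multiallelic records are skipped with a warning and half-calls are missing", {
  path <- write_mini_vcf(
    tempfile(fileext = ".vcf"), c("0|0", "0|1", "1|1"),
    extra_lines = c(
      paste(c("1", 200, "rs2", "A", "G,T", ".", "PASS", ".", "GT",
              "0|0", "1|2", "0|0"), collapse = "\t"),
      paste(c("1", 300, "rs3", "A", "G", ".", "PASS", ".", "GT",
              ".|1", "0|1", "1|1"), collapse = "\t")))
  expect_warning(gm <- load_vcf(path, maf_min = 0, miss_max = 1),
                 "multiallelic")
  expect_equal(gm$variants$vid, c("rs1", "rs3"))
  expect_true(is.na(gm$codes["rs3", 1]))  # half-call ./1 -> missing
})

test_that("MAF and missingness filters match an independent scan of the file", {
  # 200 variants / 60 samples: 30 with MAF < 0.01, 10 with missing >= 0.2
  set.seed(401)
  n_s <- 60L
  codes <- matrix(1L, 200, n_s)
  for (i in 1:160) codes[i, ] <- rbinom(n_s, 2, 0.3)
  for (i in 161:190) codes[i, ] <- c(1L, rep(0L, n_s - 1))  # MAF 1/120
  for (i in 191:200) codes[i, sample(n_s, 14)] <- NA        # 23% missing
  v <- toy_variants(seq_len(200) * 50L)
  gm0 <- genotype_matrix(v, sprintf("S%d", 1:n_s), codes)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm0, path)

  # independent oracle: raw text scan
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  pass <- vapply(lines, function(l) {
    g <- strsplit(l, "\t")[[1]][-(1:9)]
    al <- unlist(strsplit(g, "/"))
    ok <- al != "."
    f <- sum(al[ok] == "1") / sum(ok)
    miss <- mean(g == "./.")
    min(f, 1 - f) >= 0.01 && miss < 0.2
  }, TRUE)
  gm <- load_vcf(path, maf_min = 0.01, miss_max = 0.2)
  expect_equal(nrow(gm$variants), sum(pass))
  expect_equal(nrow(gm$variants), 160L)
})

test_that("VCF writing round-trips codes and phase", {
  for (phased in c(TRUE, FALSE)) {
    set.seed(if (phased) 42 else 43)
    hap <- matrix(rbinom(30 * 40, 1, 0.4), 30, 40)
    gm0 <- gm_from_haps(hap)
    if (!phased)
      gm0 <- genotype_matrix(gm0$variants[, 1:5], gm0$samples, gm0$codes)
    path <- tempfile(fileext = ".vcf")
    write_vcf(gm0, path)
    gm1 <- load_vcf(path, maf_min = 0, miss_max = 1)
    expect_equal(gm1$phased, phased)
    expect_equal(unname(gm1$codes), unname(gm0$codes))
    if (phased)
      expect_equal(unname(gm1$haplotypes), unname(gm0$haplotypes))
  }
})

test_that("reported MAF is folded and filters are monotone", {
  d <- tempfile()
  paths <- write_fixture_set(fx$man, d)
  panel <- load_panel(paths$panel)
  gm <- load_vcf(paths$vcf, maf_min = 0, miss_max = 1, panel = panel,
                 population = "CHB")
  expect_true(all(gm$variants$maf <= 0.5 + 1e-12))
  counts <- vapply(c(0, 0.05, 0.2, 0.4),
                   function(m) nrow(suppressWarnings(
                     load_vcf(paths$vcf, maf_min = m,
                              miss_max = 1))$variants), 1L)
  expect_true(all(diff(counts) <= 0))
  counts2 <- vapply(c(1, 0.5, 0.1),
                    function(m) tryCatch(
                      nrow(suppressWarnings(
                        load_vcf(paths$vcf, maf_min = 0.05,
                                 miss_max = m))$variants),
                      error = function(e) 0L), 1L)
  expect_true(all(diff(counts2) <= 0))
})

test_that("expression loading validates probes and maps genes", {
  ep <- tempfile(); mp <- tempfile()
  writeLines(c("probe\tS1\tS2\tS3",
               "P1\t0.5\t1.5\t-0.2",
               "P2\t2.0\t0.1\t0.9",
               "P3\t1.0\t1.0\t1.0"), ep)
  writeLines(c("probe\tgene", "P1\tG1", "P2\tG1"), mp)
  expect_warning(em <- load_expression(ep, mp), "absent from probe map")
  expect_equal(dim(em$values), c(2L, 3L))
  expect_equal(unname(em$probe2gene), c("G1", "G1"))

  writeLines(c("probe\tS1\tS2", "P1\t0.5\toops"), ep)
  expect_error(load_expression(ep, mp), "unparsable")
  writeLines(c("probe\tS1", "P1\t1", "P1\t2"), ep)
  expect_error(load_expression(ep, mp), "duplicate probe")
})

test_that("fixture probe map re-counts to its manifest layout", {
  man <- sim_manifest(seed = 5, populations = c(CHB = 10L),
                      n_variants = 100L, n_genes = 40L, n_probes = 50L,
                      region_length = 4e6L, n_eqtl = 0L, n_taggers = 0L,
                      n_partial_taggers = 0L)
  d <- tempfile(); paths <- write_fixture_set(man, d)
  em <- load_expression(paths$expression, paths$probe_map)
  expect_equal(length(em$probes), 50L)
  expect_equal(length(unique(em$probe2gene)), 40L)
})

test_that("panel loading rejects duplicates and resolves populations", {
  pp <- tempfile()
  writeLines(c("sample\tpopulation", "S1\tCHB", "S2\tYRI", "S1\tCHB"), pp)
  expect_error(load_panel(pp), "duplicate")
  writeLines(c("sample\tpopulation", "S1\tCHB", "S2\tYRI"), pp)
  panel <- load_panel(pp)
  expect_equal(panel_samples(panel, "CHB"), "S1")
  expect_equal(panel_samples(panel, "ALL"), c("S1", "S2"))
  expect_error(panel_samples(panel, "CEU"), "not found")
})
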