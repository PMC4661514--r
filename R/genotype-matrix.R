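#' Classify a biallelic variant as SNP or indel
#'
#' A variant is a SNP when both alleles are single bases; any length
#' difference (insertion or deletion, including large structural deletions
#' written with an anchor base) makes it an indel.
#'
#' @param ref Reference allele string(s).
#' @param alt Alternate allele string(s).
#' @return Character vector, `"SNP"` or `"INDEL"`.
#' @examples
#' classify_variant("A", "G")    # SNP
#' classify_variant("A", "AT")   # INDEL
#' classify_variant("ATG", "A")  # INDEL
#' @export
classify_variant <- function(ref, alt) {
  if (length(ref) != length(alt))
    stop2("'ref' and 'alt' must have equal length")
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop2("alleles must be nonempty")
  if (any(ref == alt))
    stop2("ref and alt alleles must differ")
  if (any(grepl(",", alt, fixed = TRUE)))
    stop2("multiallelic alt string (comma) not allowed; split upstream or drop")
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}

#' Construct a genotype matrix
#'
#' The central genotype container: an ordered variant table, sample IDs, a
#' variants x samples matrix of alt-allele counts (0/1/2, `NA` missing) and,
#' for phased data, a variants x (2 * samples) binary haplotype matrix whose
#' columns `2i - 1` and `2i` are the two haplotypes of sample `i`.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `vid`, `ref`,
#'   `alt` (and optionally `vclass`, `maf`, `missing_rate`, which are filled
#'   in if absent).
#' @param samples Character vector of sample IDs.
#' @param codes Integer matrix of alt-allele dosages, variants x samples.
#' @param phased Logical; `TRUE` when all calls are phased.
#' @param haplotypes Optional binary matrix, variants x (2 * samples).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, codes, phased = FALSE,
                            haplotypes = NULL) {
  stopifnot(is.data.frame(variants), nrow(variants) == nrow(codes),
            length(samples) == ncol(codes))
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1)) stop2("variant positions must be >= 1")
    if (is.null(variants$vclass))
      variants$vclass <- classify_variant(variants$ref, variants$alt)
  } else if (is.null(variants$vclass)) {
    variants$vclass <- character(0)
  }
  codes <- matrix(as.integer(codes), nrow = nrow(variants),
                  ncol = length(samples),
                  dimnames = list(variants$vid, samples))
  bad <- !is.na(codes) & (codes < 0L | codes > 2L)
  if (any(bad)) stop2("genotype codes must be 0, 1, 2 or NA")
  if (phased) {
    if (is.null(haplotypes))
      stop2("phased genotype_matrix requires a haplotype matrix")
    stopifnot(nrow(haplotypes) == nrow(variants),
              ncol(haplotypes) == 2L * length(samples))
    recoded <- haplotypes[, seq(1, ncol(haplotypes), 2), drop = FALSE] +
      haplotypes[, seq(2, ncol(haplotypes), 2), drop = FALSE]
    ok <- is.na(codes) | is.na(recoded) | codes == recoded
    if (!all(ok)) stop2("haplotypes inconsistent with genotype codes")
    dimnames(haplotypes) <- list(variants$vid, NULL)
  }
  gm <- structure(
    list(variants = variants, samples = samples, codes = codes,
         phased = phased, haplotypes = if (phased) haplotypes else NULL),
    class = "genotype_matrix")
  if (is.null(gm$variants$maf) && nrow(variants) > 0)
    gm$variants$maf <- variant_maf(gm)
  if (is.null(gm$variants$missing_rate) && nrow(variants) > 0)
    gm$variants$missing_rate <- rowMeans(is.na(codes))
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants (%d SNP, %d indel) x %d samples%s\n",
              nrow(x$variants), sum(x$variants$vclass == "SNP"),
              sum(x$variants$vclass == "INDEL"), length(x$samples),
              if (x$phased) ", phased" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Per-variant folded minor allele frequency
#'
#' Computed on non-missing alleles of the current sample set; always folded,
#' so the result is at most 0.5.
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector, one MAF per variant.
#' @export
variant_maf <- function(gm) {
  n_ok <- rowSums(!is.na(gm$codes))
  f <- rowSums(gm$codes, na.rm = TRUE) / (2 * n_ok)
  maf <- pmin(f, 1 - f)
  maf[n_ok == 0] <- NA_real_
  maf
}

#' Subset a genotype matrix by samples or population
#'
#' @param gm A [genotype_matrix()].
#' @param samples Sample IDs to keep, or `NULL` to select via `panel`.
#' @param panel,population Alternative selection: keep samples whose panel
#'   population is in `population` (a label vector, or `"ALL"`).
#' @param recompute_stats Recompute per-variant MAF/missingness on the subset.
#' @return A `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(gm, samples = NULL, panel = NULL,
                           population = "ALL", recompute_stats = TRUE) {
  if (is.null(samples)) {
    if (is.null(panel)) stop2("give either 'samples' or 'panel'")
    samples <- panel_samples(panel, population)
  }
  keep <- match(samples, gm$samples)
  if (anyNA(keep))
    stop2("samples not in genotype matrix: %s",
          paste(samples[is.na(keep)], collapse = ", "))
  hap <- NULL
  if (gm$phased) {
    hcols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
    hap <- gm$haplotypes[, hcols, drop = FALSE]
  }
  v <- gm$variants
  if (recompute_stats) v$maf <- v$missing_rate <- NULL
  genotype_matrix(v, gm$samples[keep],
                  gm$codes[, keep, drop = FALSE], gm$phased, hap)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCFv4.2 with GT-only genotype fields; phased matrices are
#' written with `|` separators from the haplotype matrix, unphased with `/`.
#' Round-trips through [load_vcf()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  n <- length(gm$samples)
  if (gm$phased) {
    a1 <- gm$haplotypes[, seq(1, 2 * n, 2), drop = FALSE]
    a2 <- gm$haplotypes[, seq(2, 2 * n, 2), drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), nrow = nrow(v))
    gt[is.na(a1) | is.na(a2)] <- ".|."
  } else {
    code2gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix(code2gt[as.character(gm$codes)], nrow = nrow(v))
    gt[is.na(gm$codes)] <- "./."
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eqtlexplorer",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  body <- if (nrow(v) > 0)
    paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
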