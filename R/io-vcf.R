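#' Load genotypes from a VCF into a genotype matrix
#'
#' Reads a VCF (v4.x, plain or gzipped) through \pkg{vcfR}, keeps biallelic
#' records only (multiallelic records are skipped with a warning), restricts
#' to the samples of the requested population and applies the standard
#' variant filters: folded minor allele frequency at least `maf_min` and
#' missing rate strictly below `miss_max`, both evaluated on the selected
#' samples. The matrix is flagged phased only when every retained genotype
#' call uses the `|` separator. Half-calls (e.g. `./1`) are conservatively
#' treated as missing.
#'
#' @param path VCF file path.
#' @param maf_min Minimum folded MAF (default 0.01, the usual eQTL-panel
#'   filter; use 0.001 for an LD panel).
#' @param miss_max Maximum missing rate, exclusive (default 0.2).
#' @param panel Optional sample panel (see [load_panel()]).
#' @param population Population label within `panel`, or `"ALL"`.
#' @return A [genotype_matrix()] for the selected samples; empty (with a
#'   warning) when no variant survives filtering.
#' @export
load_vcf <- function(path, maf_min = 0.01, miss_max = 0.2, panel = NULL,
                     population = "ALL") {
  if (!file.exists(path)) stop2("VCF file not found: %s", path)
  check_fraction(maf_min, "maf_min"); check_fraction(miss_max, "miss_max")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop2("VCF contains no variant records: %s", path)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    warn2("skipping %d multiallelic record(s)", sum(multi))
  keep <- !multi & !is.na(fix$ALT) & fix$ALT != "." & fix$REF != fix$ALT
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep))
  all_samples <- colnames(vcf@gt)[-1]
  colnames(gt) <- all_samples

  if (!is.null(panel)) {
    wanted <- panel_samples(panel, population)
    wanted <- intersect(wanted, all_samples)
    if (length(wanted) == 0)
      stop2("no VCF samples left after intersecting with panel population '%s'",
            paste(population, collapse = ","))
    gt <- gt[, wanted, drop = FALSE]
  }
  samples <- colnames(gt)

  parsed <- parse_gt(gt)
  codes <- parsed$codes
  phased <- parsed$all_phased

  n_ok <- rowSums(!is.na(codes))
  f_alt <- rowSums(codes, na.rm = TRUE) / (2 * n_ok)
  maf <- pmin(f_alt, 1 - f_alt)
  miss <- rowMeans(is.na(codes))
  pass <- n_ok > 0 & maf >= maf_min & miss < miss_max
  if (!any(pass)) {
    warn2("no variants pass MAF/missingness filters in %s", path)
  }

  variants <- data.frame(
    chrom = fix$CHROM[pass], pos = as.integer(fix$POS[pass]),
    vid = ifelse(is.na(fix$ID[pass]) | fix$ID[pass] == ".",
                 paste(fix$CHROM[pass], fix$POS[pass], fix$REF[pass],
                       fix$ALT[pass], sep = ":"),
                 fix$ID[pass]),
    ref = fix$REF[pass], alt = fix$ALT[pass],
    stringsAsFactors = FALSE)

  hap <- if (phased) parsed$haplotypes[pass, , drop = FALSE] else NULL
  genotype_matrix(variants, samples, codes[pass, , drop = FALSE],
                  phased = phased, haplotypes = hap)
}

# Parse a matrix of GT strings into dosage codes and (if fully phased)
# haplotype alleles. Any genotype containing '.' is missing.
parse_gt <- function(gt) {
  gt[gt == "."] <- NA_character_
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  # haploid entries (no separator) are treated as missing
  nosep <- !is.na(gt) & !grepl("[/|]", gt)
  a1[nosep] <- a2[nosep] <- NA_character_
  h1 <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt)))
  h2 <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt)))
  half <- xor(is.na(h1), is.na(h2))
  h1[half] <- h2[half] <- NA_integer_
  codes <- h1 + h2
  called <- !is.na(codes)
  all_phased <- all(grepl("|", gt[called], fixed = TRUE)) && any(called)
  haplotypes <- NULL
  if (all_phased) {
    haplotypes <- matrix(NA_integer_, nrow(gt), 2 * ncol(gt))
    haplotypes[, seq(1, 2 * ncol(gt), 2)] <- h1
    haplotypes[, seq(2, 2 * ncol(gt), 2)] <- h2
  }
  list(codes = codes, all_phased = all_phased, haplotypes = haplotypes)
}
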