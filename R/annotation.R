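# Genomic-region classification of variants relative to gene models, and
# the enrichment statistics comparing real cis-eQTLs with the permutation
# null ("fake" cis-eQTLs).

REGION_CATEGORIES <- c("TSS10K", "UTR3", "EXON", "NCRNA", "INTRON",
                       "INTERGENIC")

#' Classify variants into genomic categories
#'
#' Assigns each variant position exactly one of six mutually exclusive
#' categories, in order of precedence:
#' \describe{
#'   \item{TSS10K}{within `tss_flank` bp of any TSS (default +/- 10 kb).}
#'   \item{UTR3}{exonic in a coding gene, 3' of the CDS end (strand-aware).}
#'   \item{EXON}{exonic in a coding gene otherwise (5'UTR folds in here).}
#'   \item{NCRNA}{exonic in an ncRNA-biotype gene.}
#'   \item{INTRON}{inside a gene span but not exonic.}
#'   \item{INTERGENIC}{none of the above.}
#' }
#' The anchor gene is the one with the nearest TSS among genes overlapping
#' or flanking the variant, and `tss_distance` is the signed strand-aware
#' distance to that TSS (negative = upstream).
#'
#' @param variants Variant `data.frame` (columns `chrom`, `pos`, `vid`).
#' @param genes A [gene_model()].
#' @param tss_flank TSS flank in bp (default 10000).
#' @param precedence Category precedence, highest first (default as above).
#' @return `data.frame`: `vid`, `category`, `anchor_gene`, `tss_distance`.
#' @export
classify_region <- function(variants, genes, tss_flank = 10000L,
                            precedence = REGION_CATEGORIES) {
  stopifnot(setequal(precedence, REGION_CATEGORIES))
  gt <- genes$table
  ex <- genes$exons
  gi_ex <- match(ex$gene, gt$gene)
  n <- nrow(variants)
  category <- character(n); anchor <- rep(NA_character_, n)
  tssd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    gidx <- which(gt$chrom == chrom)
    hit <- logical(0)
    if (length(gidx) > 0) {
      d_abs <- abs(pos - gt$tss[gidx])
      inside <- pos >= pmin(gt$start[gidx], gt$end[gidx]) &
        pos <= pmax(gt$start[gidx], gt$end[gidx])
      near_tss <- d_abs <= tss_flank
      relevant <- gidx[inside | near_tss]
      if (length(relevant) > 0) {
        a <- relevant[which.min(abs(pos - gt$tss[relevant]))]
        anchor[i] <- gt$gene[a]
        tssd[i] <- if (gt$strand[a] == "+") pos - gt$tss[a] else gt$tss[a] - pos
      }
      flags <- c(TSS10K = any(near_tss), UTR3 = FALSE, EXON = FALSE,
                 NCRNA = FALSE, INTRON = FALSE, INTERGENIC = FALSE)
      for (gi in gidx[inside]) {
        g_ex <- which(gi_ex == gi & pos >= ex$start & pos <= ex$end &
                        ex$gene == gt$gene[gi])
        exonic <- length(g_ex) > 0
        if (exonic && gt$biotype[gi] == "coding") {
          in_utr3 <- if (gt$strand[gi] == "+") pos > gt$cds_end[gi]
                     else pos < gt$cds_start[gi]
          if (isTRUE(in_utr3)) flags[["UTR3"]] <- TRUE
          else flags[["EXON"]] <- TRUE
        } else if (exonic) {
          flags[["NCRNA"]] <- TRUE
        } else {
          flags[["INTRON"]] <- TRUE
        }
      }
      hit <- precedence[flags[precedence]]
    }
    category[i] <- if (length(hit) > 0) hit[1] else "INTERGENIC"
  }
  data.frame(vid = variants$vid, category = category, anchor_gene = anchor,
             tss_distance = tssd, stringsAsFactors = FALSE)
}

#' Count variants per genomic category
#'
#' @param annotation Output of [classify_region()].
#' @return Named integer vector over all six categories (zeros included).
#' @export
region_counts <- function(annotation) {
  tab <- table(factor(annotation$category, levels = REGION_CATEGORIES))
  stats::setNames(as.integer(tab), REGION_CATEGORIES)
}

#' Chi-squared enrichment of real vs. fake cis-eQTLs in one category
#'
#' 2x2 chi-squared test (category vs. not-category, real vs. fake pool),
#' without continuity correction by default (the large-count regime of
#' genome-wide pools); when any expected cell is below 5 the result is
#' flagged `small_expected`.
#'
#' @param real_counts,fake_counts Named category count vectors (see
#'   [region_counts()]), or single in-category counts when `real_total` /
#'   `fake_total` are given.
#' @param category Category to test.
#' @param real_total,fake_total Optional totals (default: sum of counts).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A one-row `data.frame`: `category`, `real_count`, `real_total`,
#'   `fake_count`, `fake_total`, `chi2`, `df`, `p`, `small_expected`.
#' @export
enrichment_test <- function(real_counts, fake_counts, category,
                            real_total = NULL, fake_total = NULL,
                            correct = FALSE) {
  pick <- function(x, tot) {
    if (length(x) > 1 || !is.null(names(x))) {
      cnt <- unname(x[[category]]); tot <- tot %||% sum(x)
    } else {
      cnt <- x
      if (is.null(tot)) stop2("scalar counts need an explicit total")
    }
    c(cnt, tot)
  }
  r <- pick(real_counts, real_total); f <- pick(fake_counts, fake_total)
  if (r[2] <= 0 || f[2] <= 0) stop2("both totals must be > 0")
  tab <- rbind(real = c(r[1], r[2] - r[1]), fake = c(f[1], f[2] - f[1]))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  data.frame(category = category, real_count = r[1], real_total = r[2],
             fake_count = f[1], fake_total = f[2],
             chi2 = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value, small_expected = any(expected < 5),
             stringsAsFactors = FALSE)
}

#' Compare MAF distributions of two cis-eQTL groups
#'
#' Two-sample Student's t-test (equal-variance by default, Welch optional),
#' e.g. population-shared vs. population-specific cis-eQTL MAFs.
#'
#' @param maf1,maf2 Numeric MAF vectors, each of length >= 2.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A list: `t`, `df`, `p`, `mean1`, `mean2` (`t`/`p` are `NA` when
#'   both groups have zero variance).
#' @export
maf_compare <- function(maf1, maf2, var_equal = TRUE) {
  if (length(maf1) < 2 || length(maf2) < 2)
    stop2("both groups need n >= 2")
  if (sd(maf1) == 0 && sd(maf2) == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean1 = mean(maf1), mean2 = mean(maf2)))
  res <- t.test(maf1, maf2, var.equal = var_equal)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean1 = mean(maf1), mean2 = mean(maf2))
}

#' Compare per-population indel/SNP ratios between sharing subsections
#'
#' Paired t-test by default (the same populations contribute one
#' specific-subsection and one shared-subsection ratio each); unpaired
#' optional. For the paired test the two vectors must cover the same
#' populations (matched by name when named).
#'
#' @param ratio_specific,ratio_shared Per-population indel/SNP ratio
#'   vectors (length >= 2; named by population for safe pairing).
#' @param paired Paired test (default `TRUE`).
#' @return A list: `t`, `df`, `p`, `mean_specific`, `mean_shared`.
#' @export
ratio_compare <- function(ratio_specific, ratio_shared, paired = TRUE) {
  if (length(ratio_specific) < 2 || length(ratio_shared) < 2)
    stop2("need ratios from at least 2 populations per group")
  if (paired) {
    if (length(ratio_specific) != length(ratio_shared))
      stop2("paired comparison needs the same populations in both groups")
    if (!is.null(names(ratio_specific)) && !is.null(names(ratio_shared))) {
      if (!setequal(names(ratio_specific), names(ratio_shared)))
        stop2("paired comparison needs the same populations in both groups")
      ratio_shared <- ratio_shared[names(ratio_specific)]
    }
  }
  if (paired && sd(ratio_specific - ratio_shared) == 0) {
    d <- mean(ratio_specific - ratio_shared)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(ratio_specific) - 1,
                p = if (d == 0) 1 else 0,
                mean_specific = mean(ratio_specific),
                mean_shared = mean(ratio_shared)))
  }
  res <- t.test(ratio_specific, ratio_shared, paired = paired,
                var.equal = !paired)
  list(t = unname(res$statistic), df = unname(res$parameter), p = res$p.value,
       mean_specific = mean(ratio_specific), mean_shared = mean(ratio_shared))
}

#' Overlap variants with regulatory feature intervals
#'
#' A SNP overlaps a feature when its position lies inside the interval; an
#' indel overlaps when any base of its reference span does (POS through
#' POS + nchar(ref) - 1, the anchored-deletion convention).
#'
#' @param variants Variant `data.frame` (columns `chrom`, `pos`, `vid`,
#'   `ref`).
#' @param regbed `GRanges` of regulatory features (see
#'   [load_regulatory_bed()]).
#' @return Named list, variant ID -> character vector of overlapping
#'   feature IDs (empty when none).
#' @export
regulatory_overlap <- function(variants, regbed) {
  end <- variants$pos + nchar(variants$ref) - 1L
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, end))
  ov <- GenomicRanges::findOverlaps(v_gr, regbed, ignore.strand = TRUE)
  feats <- S4Vectors::mcols(regbed)$feature
  out <- rep(list(character(0)), nrow(variants))
  names(out) <- variants$vid
  hits <- split(feats[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  for (q in names(hits)) out[[as.integer(q)]] <- unname(hits[[q]])
  out
}
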