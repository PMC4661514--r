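# Cis-window enumeration and the per-population eQTL scan. A "cis-eQTL" is
# a variant-probe pair: the same variant can be an eQTL for several probes
# of one gene, and gene-level views are derived afterwards.

#' Enumerate variant-probe pairs in the cis window
#'
#' A variant is in cis to a gene when its position falls in the closed
#' interval `[gene_start - window, gene_end + window]` (anchor `"span"`,
#' the default) or `[tss - window, tss + window]` (anchor `"tss"`). Gene
#' pairs are expanded to probe pairs through the probe-to-gene map.
#'
#' @param genes A [gene_model()].
#' @param variants Variant `data.frame` (columns `chrom`, `pos`, `vid`).
#' @param window Cis window in bp (default 200000).
#' @param probe2gene Optional named vector probe -> gene; when given, pairs
#'   are expanded to the probe level.
#' @param anchor `"span"` or `"tss"`.
#' @return `data.frame` with columns `vid`, `gene` (and `probe` when
#'   `probe2gene` is supplied).
#' @export
cis_pairs <- function(genes, variants, window = 200000L, probe2gene = NULL,
                      anchor = c("span", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(window > 0)
  gt <- genes$table
  shared_chr <- intersect(unique(gt$chrom), unique(variants$chrom))
  if (length(shared_chr) == 0 && nrow(gt) > 0 && nrow(variants) > 0)
    stop2("no shared chromosome names between gene model (%s) and variants (%s)",
          paste(unique(gt$chrom), collapse = ","),
          paste(unique(variants$chrom), collapse = ","))
  lo <- if (anchor == "span") pmin(gt$start, gt$end) - window else gt$tss - window
  hi <- if (anchor == "span") pmax(gt$start, gt$end) + window else gt$tss + window
  g_gr <- GenomicRanges::GRanges(gt$chrom,
                                 IRanges::IRanges(pmax(lo, 1L), hi))
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
  ov <- GenomicRanges::findOverlaps(v_gr, g_gr, ignore.strand = TRUE)
  pairs <- data.frame(vid = variants$vid[S4Vectors::queryHits(ov)],
                      gene = gt$gene[S4Vectors::subjectHits(ov)],
                      stringsAsFactors = FALSE)
  if (!is.null(probe2gene)) {
    pm <- data.frame(probe = names(probe2gene), gene = unname(probe2gene),
                     stringsAsFactors = FALSE)
    pairs <- merge(pairs, pm, by = "gene", sort = FALSE)
    pairs <- pairs[, c("vid", "gene", "probe")]
  }
  pairs[order(match(pairs$vid, variants$vid)), , drop = FALSE]
}

#' Scan for cis-eQTLs in one population
#'
#' Runs the five-model minimum-P engine over every cis variant-probe pair
#' for the samples of `population` and keeps pairs with `min_p < cutoff`.
#'
#' @param gm A [genotype_matrix()] (all populations).
#' @param em An [expression_matrix()].
#' @param genes A [gene_model()].
#' @param panel A sample panel (see [load_panel()]).
#' @param population Population label, or `"ALL"`.
#' @param window Cis window in bp.
#' @param cutoff Keep records with `min_p < cutoff` (default `1e-2`, the
#'   database cutoff; use `1e-4` for distribution analyses).
#' @param anchor Window anchor, `"span"` or `"tss"` (see [cis_pairs()]).
#' @param min_samples Minimum shared genotype/expression samples (default 10).
#' @return `data.frame` of cis-eQTL records ordered by (chrom, pos, probe):
#'   `vid`, `chrom`, `pos`, `vclass`, `maf`, `probe`, `gene`, `population`,
#'   `min_p`, `best_model`, `beta`, `n_used`, `tss_distance`,
#'   `passes_relaxed` (`min_p < 1e-2`), `passes_strict` (`min_p < 1e-4`).
#' @export
cis_scan <- function(gm, em, genes, panel = NULL, population = "ALL",
                     window = 200000L, cutoff = 1e-2,
                     anchor = c("span", "tss"), min_samples = 10L) {
  anchor <- match.arg(anchor)
  if (!is_fraction(cutoff) || cutoff <= 0)
    stop2("'cutoff' must be in (0, 1]")
  pop_samples <- if (is.null(panel)) gm$samples
                 else intersect(panel_samples(panel, population), gm$samples)
  shared <- intersect(pop_samples, em$samples)
  if (length(shared) == 0) stop2("no shared samples between genotypes and expression")
  if (length(shared) < min_samples)
    stop2("only %d shared samples; minimum is %d", length(shared), min_samples)

  gsub_ <- subset_samples(gm, samples = shared)
  codes <- gsub_$codes
  ev <- em$values[, shared, drop = FALSE]
  keep_probe <- !is.na(em$probe2gene) &
    apply(ev, 1, function(x) stats::var(x, na.rm = TRUE) > 0)
  ev <- ev[keep_probe, , drop = FALSE]
  p2g <- em$probe2gene[rownames(ev)]

  pairs <- cis_pairs(genes, gsub_$variants, window = window,
                     probe2gene = p2g, anchor = anchor)
  if (nrow(pairs) == 0)
    return(empty_records())

  vi <- match(pairs$vid, gsub_$variants$vid)
  pi_ <- match(pairs$probe, rownames(ev))
  popl <- if (identical(population, "ALL")) "ALL"
          else paste(population, collapse = "+")

  n <- nrow(pairs)
  min_p <- numeric(n); best <- character(n); beta <- numeric(n)
  n_used <- integer(n)
  for (k in seq_len(n)) {
    f <- fit_five(ev[pi_[k], ], codes[vi[k], ])
    p <- f$p
    if (all(is.na(p))) { min_p[k] <- NA_real_; best[k] <- NA_character_
      beta[k] <- NA_real_; n_used[k] <- f$n_used; next }
    b <- which.min(p)
    min_p[k] <- p[[b]]; best[k] <- names(p)[b]
    beta[k] <- f$beta[[b]]; n_used[k] <- f$n_used
  }

  gtab <- genes$table
  gi <- match(pairs$gene, gtab$gene)
  v <- gsub_$variants[vi, ]
  tssd <- ifelse(gtab$strand[gi] == "+", v$pos - gtab$tss[gi],
                 gtab$tss[gi] - v$pos)
  rec <- data.frame(
    vid = v$vid, chrom = v$chrom, pos = v$pos, vclass = v$vclass,
    maf = v$maf, probe = pairs$probe, gene = pairs$gene,
    population = popl, min_p = min_p, best_model = best, beta = beta,
    n_used = n_used, tss_distance = tssd,
    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$min_p) & rec$min_p < cutoff, , drop = FALSE]
  rec$passes_relaxed <- rec$min_p < 1e-2
  rec$passes_strict <- rec$min_p < 1e-4
  rec <- rec[order(rec$chrom, rec$pos, rec$probe), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

empty_records <- function() {
  data.frame(vid = character(0), chrom = character(0), pos = integer(0),
             vclass = character(0), maf = numeric(0), probe = character(0),
             gene = character(0), population = character(0),
             min_p = numeric(0), best_model = character(0),
             beta = numeric(0), n_used = integer(0),
             tss_distance = numeric(0), passes_relaxed = logical(0),
             passes_strict = logical(0), stringsAsFactors = FALSE)
}

#' Scan all populations of a panel
#'
#' Convenience wrapper running [cis_scan()] once per population and binding
#' the records into one eQTL database table.
#'
#' @inheritParams cis_scan
#' @param populations Labels to scan (default: all panel populations).
#' @return Combined record `data.frame` (see [cis_scan()]).
#' @export
cis_scan_all <- function(gm, em, genes, panel, populations = NULL,
                         window = 200000L, cutoff = 1e-2,
                         anchor = c("span", "tss"), min_samples = 10L) {
  anchor <- match.arg(anchor)
  populations <- populations %||% unique(panel$population)
  out <- lapply(populations, function(p)
    cis_scan(gm, em, genes, panel, p, window, cutoff, anchor, min_samples))
  do.call(rbind, out)
}

#' Label population sharing of cis-eQTL pairs
#'
#' A (variant, probe) pair passing the active cutoff in at least two
#' populations is population-shared; in exactly one, population-specific.
#'
#' @param records cis-eQTL record table (from [cis_scan_all()]).
#' @param cutoff Active cutoff re-applied before counting populations
#'   (default: keep all records present).
#' @return `records` with added columns `n_pops`, `populations` (comma
#'   string) and `sharing` (`"shared"`/`"specific"`); records not passing
#'   `cutoff` are dropped.
#' @export
classify_sharing <- function(records, cutoff = NULL) {
  if (!is.null(cutoff)) records <- records[records$min_p < cutoff, , drop = FALSE]
  if (nrow(records) == 0) {
    records$n_pops <- integer(0); records$populations <- character(0)
    records$sharing <- character(0); return(records)
  }
  key <- paste(records$vid, records$probe, sep = "\r")
  pops_by <- lapply(split(records$population, key), function(p) sort(unique(p)))
  n_pops <- vapply(pops_by, length, 1L)[key]
  records$n_pops <- unname(n_pops)
  records$populations <- unname(vapply(pops_by, paste, "", collapse = ",")[key])
  records$sharing <- ifelse(records$n_pops >= 2, "shared", "specific")
  records
}

#' Flag peak cis-eQTLs
#'
#' Per (probe, population, variant class), flags the record with the
#' smallest min-P; ties are broken by smaller genomic position. Idempotent.
#'
#' @param records cis-eQTL record table.
#' @return `records` with a logical `is_peak` column.
#' @export
peak_reduce <- function(records) {
  if (nrow(records) == 0) { records$is_peak <- logical(0); return(records) }
  key <- paste(records$probe, records$population, records$vclass, sep = "\r")
  ord <- order(key, records$min_p, records$pos)
  first <- !duplicated(key[ord])
  is_peak <- logical(nrow(records))
  is_peak[ord] <- first
  records$is_peak <- is_peak
  records
}

#' Summarize sharing and indel/SNP composition of an eQTL table
#'
#' @param records cis-eQTL record table with sharing labels (see
#'   [classify_sharing()]); pass peak-reduced records to obtain the
#'   peak-only ratios.
#' @return A list of class `sharing_summary`:
#'   \describe{
#'     \item{by_class}{per variant class: unique pairs, shared pairs and
#'       shared percentage (printed to 1 decimal).}
#'     \item{by_population}{per population and class: record counts,
#'       specific/shared splits and the indel/SNP count ratios overall, in
#'       the specific and in the shared subsections.}
#'     \item{pairwise_exclusive}{pairs shared by exactly two populations,
#'       counted per population pair and class.}
#'   }
#' @export
sharing_summary <- function(records) {
  stopifnot("sharing" %in% names(records))
  key <- paste(records$vid, records$probe, sep = "\r")
  pair_first <- !duplicated(key)
  pairs <- records[pair_first, c("vclass", "sharing", "n_pops", "populations")]

  by_class <- do.call(rbind, lapply(c("INDEL", "SNP"), function(vc) {
    tot <- sum(pairs$vclass == vc)
    sh <- sum(pairs$vclass == vc & pairs$sharing == "shared")
    data.frame(vclass = vc, n_pairs = tot, n_shared = sh,
               shared_pct = pct(sh, tot), stringsAsFactors = FALSE)
  }))

  pops <- sort(unique(records$population))
  by_population <- do.call(rbind, lapply(pops, function(p) {
    r <- records[records$population == p, ]
    n_ind <- sum(r$vclass == "INDEL"); n_snp <- sum(r$vclass == "SNP")
    ns <- function(vc, sh) sum(r$vclass == vc & r$sharing == sh)
    ratio <- function(a, b) if (b == 0) NA_real_ else a / b
    data.frame(
      population = p, n_indel = n_ind, n_snp = n_snp,
      indel_specific = ns("INDEL", "specific"),
      indel_shared = ns("INDEL", "shared"),
      snp_specific = ns("SNP", "specific"), snp_shared = ns("SNP", "shared"),
      shared_pct = pct(ns("INDEL", "shared") + ns("SNP", "shared"),
                       n_ind + n_snp),
      specific_pct = pct(ns("INDEL", "specific") + ns("SNP", "specific"),
                         n_ind + n_snp),
      indel_snp_ratio = ratio(n_ind, n_snp),
      indel_snp_ratio_specific = ratio(ns("INDEL", "specific"),
                                       ns("SNP", "specific")),
      indel_snp_ratio_shared = ratio(ns("INDEL", "shared"), ns("SNP", "shared")),
      stringsAsFactors = FALSE)
  }))

  two <- pairs[pairs$n_pops == 2, ]
  pairwise_exclusive <- if (nrow(two) > 0) {
    agg <- aggregate(list(n = rep(1L, nrow(two))),
                     by = list(populations = two$populations,
                               vclass = two$vclass), FUN = sum)
    agg[order(-agg$n), ]
  } else data.frame(populations = character(0), vclass = character(0),
                    n = integer(0))

  structure(list(by_class = by_class, by_population = by_population,
                 pairwise_exclusive = pairwise_exclusive),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat("cis-eQTL sharing summary\n\nBy variant class:\n")
  print(x$by_class, row.names = FALSE)
  cat("\nBy population:\n")
  print(x$by_population, row.names = FALSE)
  if (nrow(x$pairwise_exclusive) > 0) {
    cat("\nExclusive two-population sharing (top):\n")
    print(utils::head(x$pairwise_exclusive, 10), row.names = FALSE)
  }
  invisible(x)
}
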