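#' Construct a gene model set
#'
#' Internal coordinates are 1-based closed. The TSS is the strand-aware 5'
#' end (`start` for `+` genes, `end` for `-` genes); conversions from 0-based
#' BED happen only in the loaders.
#'
#' @param table `data.frame` with columns `gene`, `chrom`, `strand`,
#'   `start`, `end`, `cds_start`, `cds_end` (NA for non-coding),
#'   `biotype` (`"coding"` or `"ncRNA"`).
#' @param exons `data.frame` with columns `gene`, `start`, `end` (1-based
#'   closed, non-overlapping within a gene).
#' @return An object of class `gene_model`, with derived `tss`/`tes` columns.
#' @export
gene_model <- function(table, exons) {
  need <- c("gene", "chrom", "strand", "start", "end", "biotype")
  if (!all(need %in% names(table)))
    stop2("gene table must have columns: %s", paste(need, collapse = ", "))
  if (!all(table$strand %in% c("+", "-")))
    stop2("gene strand must be '+' or '-'")
  if (!all(table$biotype %in% c("coding", "ncRNA")))
    stop2("gene biotype must be 'coding' or 'ncRNA'")
  if (is.null(table$cds_start)) table$cds_start <- NA_integer_
  if (is.null(table$cds_end)) table$cds_end <- NA_integer_
  coding <- table$biotype == "coding"
  if (any(coding & (is.na(table$cds_start) | is.na(table$cds_end))))
    stop2("coding genes need cds_start/cds_end")
  if (any(coding & (table$cds_start < table$start | table$cds_end > table$end)))
    stop2("CDS outside gene span")
  table$tss <- ifelse(table$strand == "+", table$start, table$end)
  table$tes <- ifelse(table$strand == "+", table$end, table$start)
  exons <- exons[order(match(exons$gene, table$gene), exons$start), ,
                 drop = FALSE]
  sp <- split(seq_len(nrow(exons)), exons$gene)
  for (idx in sp) {
    if (length(idx) > 1 &&
        any(exons$start[idx][-1] <= exons$end[idx][-length(idx)]))
      stop2("overlapping exons in gene %s", exons$gene[idx[1]])
  }
  structure(list(table = table, exons = exons), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes (%d coding, %d ncRNA), %d exons\n",
              nrow(x$table), sum(x$table$biotype == "coding"),
              sum(x$table$biotype == "ncRNA"), nrow(x$exons)))
  invisible(x)
}

#' Load gene models from BED12 or GTF
#'
#' BED12: the `name` field is the gene ID, blocks are exons, and
#' `thickStart`/`thickEnd` delimit the CDS — a zero-width thick interval
#' marks a non-coding (ncRNA) gene, the usual BED convention. GTF: `gene`,
#' `exon` and `CDS` features are used, with the `gene_biotype` attribute
#' (anything other than `protein_coding` is treated as ncRNA). Import goes
#' through \pkg{rtracklayer}, so BED's 0-based half-open coordinates arrive
#' converted to the 1-based closed internal convention.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"auto"`, `"bed"` or `"gtf"`.
#' @return A [gene_model()].
#' @export
load_genes <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  if (format == "bed") load_genes_bed12(path) else load_genes_gtf(path)
}

load_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$blocks))
    stop2("gene BED must be BED12 (12 columns with exon blocks): %s", path)
  thick <- md$thick
  noncoding <- IRanges::width(thick) == 0
  table <- data.frame(
    gene = md$name, chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    cds_start = ifelse(noncoding, NA_integer_, IRanges::start(thick)),
    cds_end = ifelse(noncoding, NA_integer_, IRanges::end(thick)),
    biotype = ifelse(noncoding, "ncRNA", "coding"),
    stringsAsFactors = FALSE)
  if (any(!table$strand %in% c("+", "-")))
    stop2("gene BED12 records must carry a +/- strand")
  blocks <- md$blocks  # exon ranges relative to the gene start (1-based)
  n_ex <- S4Vectors::elementNROWS(blocks)
  flat <- unlist(blocks)
  exons <- data.frame(
    gene = rep(table$gene, n_ex),
    start = rep(table$start, n_ex) + IRanges::start(flat) - 1L,
    end = rep(table$start, n_ex) + IRanges::end(flat) - 1L,
    stringsAsFactors = FALSE)
  gene_model(table, exons)
}

load_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$type) || is.null(md$gene_id))
    stop2("GTF must carry 'type' and 'gene_id' attributes: %s", path)
  gid <- as.character(md$gene_id)
  is_gene <- md$type == "gene"
  if (!any(is_gene)) stop2("no 'gene' features in GTF: %s", path)
  biot <- if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
          else rep("protein_coding", length(gr))
  cds <- gr[md$type == "CDS"]
  cds_by <- split(cds, gid[md$type == "CDS"])
  g <- gr[is_gene]
  gg <- gid[is_gene]
  has_cds <- gg %in% names(cds_by)
  cds_start <- rep(NA_integer_, length(g)); cds_end <- rep(NA_integer_, length(g))
  if (any(has_cds)) {
    cds_start[has_cds] <- vapply(cds_by[gg[has_cds]],
                                 function(x) min(GenomicRanges::start(x)), 1L)
    cds_end[has_cds] <- vapply(cds_by[gg[has_cds]],
                               function(x) max(GenomicRanges::end(x)), 1L)
  }
  table <- data.frame(
    gene = gg, chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    cds_start = cds_start, cds_end = cds_end,
    biotype = ifelse(biot[is_gene] == "protein_coding" & has_cds,
                     "coding", "ncRNA"),
    stringsAsFactors = FALSE)
  ex <- gr[md$type == "exon"]
  exr <- GenomicRanges::reduce(S4Vectors::split(ex, gid[md$type == "exon"]))
  flat <- unlist(exr)
  exons <- data.frame(gene = names(flat),
                      start = GenomicRanges::start(flat),
                      end = GenomicRanges::end(flat),
                      stringsAsFactors = FALSE)
  gene_model(table, exons)
}

#' Load regulatory feature intervals from a BED file
#'
#' @param path BED file (>= 3 columns; column 4, when present, names the
#'   feature). Coordinates are converted from BED's 0-based half-open to the
#'   1-based closed internal convention by \pkg{rtracklayer}.
#' @return A `GRanges` with a `feature` metadata column.
#' @export
load_regulatory_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop2("malformed BED '%s': %s", path,
                                           conditionMessage(e)))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm))
    nm <- paste0("feature_", seq_along(gr))
  S4Vectors::mcols(gr)$feature <- nm
  gr
}
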