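# GWAS catalog intersection with the cis-eQTL database, indel tagger
# discovery and per-SNP functional reports.

#' Intersect a GWAS catalog with the cis-eQTL database
#'
#' Reports (a) catalog coverage — the fraction of catalog SNPs present in
#' the genotype panel, (b) the fraction of present SNPs that are SNP
#' cis-eQTLs at the active cutoff (GWAS eSNPs) and (c) the count and
#' fraction of traits with at least one eSNP.
#'
#' @param catalog GWAS catalog `data.frame` (`rsid`, `trait`; see
#'   [load_gwas_catalog()]).
#' @param records cis-eQTL record table (see [cis_scan_all()]).
#' @param panel_variants Character vector of variant IDs present in the
#'   genotype panel (e.g. `gm$variants$vid`).
#' @param cutoff Active cis-eQTL cutoff (default `1e-2`, the database
#'   cutoff).
#' @return A list of class `catalog_intersection`: `summary` (one-row
#'   `data.frame` with counts and percentages printed to catalog precision)
#'   and `hits` (per-eSNP record table).
#' @export
catalog_intersect <- function(catalog, records, panel_variants,
                              cutoff = 1e-2) {
  if (nrow(catalog) == 0) stop2("empty GWAS catalog")
  rsids <- unique(catalog$rsid)
  n_catalog <- length(rsids)
  present <- rsids[rsids %in% panel_variants]
  n_present <- length(present)
  pass <- records[records$min_p < cutoff & records$vclass == "SNP", ,
                  drop = FALSE]
  esnps <- present[present %in% pass$vid]
  n_esnp <- length(esnps)
  hits <- pass[pass$vid %in% esnps, , drop = FALSE]
  n_traits <- length(unique(catalog$trait))
  traits_hit <- unique(catalog$trait[catalog$rsid %in% esnps])
  summary <- data.frame(
    n_catalog = n_catalog, n_present = n_present,
    coverage_pct = pct(n_present, n_catalog),
    n_esnp = n_esnp, esnp_pct = pct(n_esnp, n_present, 2),
    n_genes = length(unique(hits$gene)),
    n_traits = n_traits, n_traits_esnp = length(traits_hit),
    traits_esnp_pct = pct(length(traits_hit), n_traits, 2),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, esnps = esnps, hits = hits,
                 traits_hit = traits_hit),
            class = "catalog_intersection")
}

#' @export
print.catalog_intersection <- function(x, ...) {
  s <- x$summary
  cat(sprintf("GWAS catalog intersection:\n  %d / %d catalog SNPs in panel (%.1f%%)\n",
              s$n_present, s$n_catalog, s$coverage_pct))
  cat(sprintf("  %d / %d present SNPs are cis-eQTLs (%.2f%%) for %d genes\n",
              s$n_esnp, s$n_present, s$esnp_pct, s$n_genes))
  cat(sprintf("  %d / %d traits with >= 1 eSNP (%.2f%%)\n",
              s$n_traits_esnp, s$n_traits, s$traits_esnp_pct))
  invisible(x)
}

#' Find indel cis-eQTL taggers of GWAS eSNPs
#'
#' For each query eSNP, searches high-LD proxies in the proxy window and
#' keeps indel proxies that are themselves cis-eQTLs at the active cutoff
#' in any population. LD is computed per population (with any-population
#' aggregation) when `panel` is given, or on the pooled sample set
#' otherwise.
#'
#' @param esnps Character vector of eSNP variant IDs (present in `gm`).
#' @param records cis-eQTL record table.
#' @param gm A [genotype_matrix()].
#' @param panel Optional panel for per-population LD.
#' @param window Proxy window total span in bp (default 1e6).
#' @param r2_min Tagger threshold (default 0.7).
#' @param cutoff Active cis-eQTL cutoff for the indel (default `1e-2`).
#' @return A list of class `tagger_table`: `taggers` (`data.frame` with
#'   `esnp`, `indel`, `r2`, `dprime`, `population`) and `summary` (see
#'   [tagger_summary()]).
#' @export
find_indel_taggers <- function(esnps, records, gm, panel = NULL,
                               window = 1e6, r2_min = 0.7, cutoff = 1e-2) {
  missing_ids <- setdiff(esnps, gm$variants$vid)
  if (length(missing_ids) > 0)
    stop2("eSNP(s) absent from genotype panel: %s",
          paste(missing_ids, collapse = ", "))
  indel_eqtls <- unique(records$vid[records$vclass == "INDEL" &
                                      records$min_p < cutoff])
  pops <- if (is.null(panel)) list(ALL = gm$samples)
          else split(panel$sample, panel$population)
  rows <- list()
  for (pn in names(pops)) {
    gmp <- subset_samples(gm, samples = intersect(pops[[pn]], gm$samples))
    for (s in esnps) {
      px <- proxy_search(s, gmp, window = window, r2_min = r2_min)
      px <- px[px$vclass == "INDEL" & px$vid %in% indel_eqtls, ,
               drop = FALSE]
      if (nrow(px) > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          esnp = s, indel = px$vid, r2 = px$r2, dprime = px$dprime,
          population = pn, stringsAsFactors = FALSE)
    }
  }
  taggers <- if (length(rows) > 0) do.call(rbind, rows)
             else data.frame(esnp = character(0), indel = character(0),
                             r2 = numeric(0), dprime = numeric(0),
                             population = character(0))
  perfect <- taggers[taggers$r2 >= 1 - 1e-12, , drop = FALSE]
  summary <- tagger_summary(
    n_esnps = length(esnps),
    n_tagged_high = length(unique(taggers$esnp)),
    n_indel_high = length(unique(taggers$indel)),
    n_tagged_perfect = length(unique(perfect$esnp)),
    n_indel_perfect = length(unique(perfect$indel)))
  structure(list(taggers = taggers, summary = summary),
            class = "tagger_table")
}

#' Tagger count summary with printed percentages
#'
#' The arithmetic layer of [find_indel_taggers()]: turns tagger marginal
#' counts into the summary percentages (fraction of eSNPs tagged at
#' `r2 >= r2_min` and at `r2 = 1`).
#'
#' @param n_esnps Total query eSNPs.
#' @param n_tagged_high eSNPs with >= 1 indel tagger at the r2 threshold.
#' @param n_indel_high Distinct indel taggers at the r2 threshold.
#' @param n_tagged_perfect eSNPs with >= 1 perfect (r2 = 1) indel tagger.
#' @param n_indel_perfect Distinct perfect indel taggers.
#' @return One-row `data.frame` with the counts plus `tagged_high_pct` and
#'   `tagged_perfect_pct` (1 decimal).
#' @export
tagger_summary <- function(n_esnps, n_tagged_high, n_indel_high = NA_integer_,
                           n_tagged_perfect = 0L,
                           n_indel_perfect = NA_integer_) {
  data.frame(n_esnps = n_esnps, n_tagged_high = n_tagged_high,
             n_indel_high = n_indel_high,
             tagged_high_pct = pct(n_tagged_high, n_esnps),
             n_tagged_perfect = n_tagged_perfect,
             n_indel_perfect = n_indel_perfect,
             tagged_perfect_pct = pct(n_tagged_perfect, n_esnps),
             stringsAsFactors = FALSE)
}

#' @export
print.tagger_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("indel taggers: %d eSNPs queried; %d tagged at high LD (%.1f%%), %d in perfect LD (%.1f%%)\n",
              s$n_esnps, s$n_tagged_high, s$tagged_high_pct,
              s$n_tagged_perfect, s$tagged_perfect_pct))
  invisible(x)
}

#' Assemble per-query functional tag reports
#'
#' The explorer front end: for each query (a dbSNP-style variant ID, or a
#' region `"chrom:start-end"` resolving to every panel variant inside),
#' combines high-LD proxy search, cis-eQTL lookup, genomic-region
#' classification and regulatory-feature overlap. A proxy that is both a
#' cis-eQTL and overlaps a regulatory feature is flagged `prioritized`.
#'
#' @param queries Character vector of variant IDs and/or `chrom:start-end`
#'   ranges.
#' @param gm A [genotype_matrix()].
#' @param records cis-eQTL record table.
#' @param genes A [gene_model()].
#' @param regbed Optional regulatory `GRanges` (see
#'   [load_regulatory_bed()]).
#' @param catalog Optional GWAS catalog (`rsid`, `trait`).
#' @param window,r2_min Proxy search parameters (defaults 1e6 bp, 0.7).
#' @param cutoff Active cis-eQTL cutoff (default `1e-2`).
#' @return A list of class `tag_report_set`; one `tag_report` per query
#'   with fields `query`, `found_in_panel`, `traits`, `eqtl_hits`,
#'   `proxies` (with region/regulatory/eQTL columns), `indel_taggers`,
#'   `perfect_taggers`.
#' @export
explore <- function(queries, gm, records, genes, regbed = NULL,
                    catalog = NULL, window = 1e6, r2_min = 0.7,
                    cutoff = 1e-2) {
  resolved <- list()
  for (q in queries) {
    if (grepl("^[^:]+:[0-9]+-[0-9]+$", q)) {
      chrom <- sub(":.*$", "", q)
      se <- as.integer(strsplit(sub("^[^:]+:", "", q), "-")[[1]])
      ids <- gm$variants$vid[gm$variants$chrom == chrom &
                               gm$variants$pos >= se[1] &
                               gm$variants$pos <= se[2]]
      if (length(ids) == 0)
        warn2("range query '%s' covers no panel variants", q)
      resolved[[q]] <- ids
    } else {
      resolved[[q]] <- q
    }
  }
  flat <- unique(unlist(resolved))
  if (length(flat) == 0) stop2("no query could be resolved to any variant")
  pass <- records[records$min_p < cutoff, , drop = FALSE]
  reports <- lapply(flat, function(q) {
    found <- q %in% gm$variants$vid
    traits <- if (!is.null(catalog)) unique(catalog$trait[catalog$rsid == q])
              else character(0)
    if (!found)
      return(structure(list(query = q, found_in_panel = FALSE,
                            traits = traits, eqtl_hits = pass[0, ],
                            proxies = NULL, indel_taggers = character(0),
                            perfect_taggers = character(0)),
                       class = "tag_report"))
    px <- proxy_search(q, gm, window = window, r2_min = r2_min)
    ann <- classify_region(
      gm$variants[match(px$vid, gm$variants$vid), , drop = FALSE], genes)
    px$category <- ann$category
    px$tss_distance <- ann$tss_distance
    px$is_eqtl <- px$vid %in% pass$vid
    reg <- if (!is.null(regbed))
      regulatory_overlap(gm$variants[match(px$vid, gm$variants$vid), ,
                                     drop = FALSE], regbed)
      else rep(list(character(0)), nrow(px))
    px$regulatory <- vapply(reg, paste, "", collapse = ",")
    px$prioritized <- px$is_eqtl & nzchar(px$regulatory)
    indel_t <- px$vid[px$vclass == "INDEL" & px$is_eqtl]
    perfect_t <- px$vid[px$vclass == "INDEL" & px$is_eqtl &
                          px$r2 >= 1 - 1e-12]
    structure(list(query = q, found_in_panel = TRUE, traits = traits,
                   eqtl_hits = pass[pass$vid == q, , drop = FALSE],
                   proxies = px, indel_taggers = indel_t,
                   perfect_taggers = perfect_t),
              class = "tag_report")
  })
  names(reports) <- flat
  structure(reports, class = "tag_report_set")
}

#' @export
print.tag_report <- function(x, ...) {
  cat(sprintf("tag_report %s: %s\n", x$query,
              if (x$found_in_panel) sprintf(
                "%d proxies, %d eQTL hit(s), %d indel tagger(s) (%d perfect)",
                NROW(x$proxies), nrow(x$eqtl_hits),
                length(x$indel_taggers), length(x$perfect_taggers))
              else "not found in genotype panel"))
  if (length(x$traits) > 0)
    cat(sprintf("  traits: %s\n", paste(x$traits, collapse = "; ")))
  invisible(x)
}

#' @export
print.tag_report_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Flatten a tag report set to a TSV-ready table
#'
#' @param reports A `tag_report_set` from [explore()].
#' @return `data.frame`, one row per (query, proxy).
#' @export
reports_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (!r$found_in_panel || NROW(r$proxies) == 0) return(NULL)
    cbind(query = r$query, r$proxies, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query = character(0), vid = character(0))
  rownames(out) <- NULL
  out
}

#' Export tag reports as a UCSC custom track (BED9)
#'
#' One record per proxy, 0-based half-open coordinates (indels span their
#' reference allele), with itemRgb encoding the functional class:
#' red = cis-eQTL + regulatory, orange = cis-eQTL, blue = regulatory,
#' grey = neither.
#'
#' @param reports A `tag_report_set` from [explore()].
#' @param path Output file.
#' @param gm The [genotype_matrix()] used to build the reports (for ref
#'   allele lengths).
#' @param name Track name.
#' @return `path`, invisibly.
#' @export
export_track <- function(reports, path, gm, name = "eqtlexplorer") {
  tab <- reports_table(reports)
  if (nrow(tab) == 0) stop2("no proxies to export")
  vi <- match(tab$vid, gm$variants$vid)
  ref_len <- nchar(gm$variants$ref[vi])
  start0 <- tab$pos - 1L
  end <- tab$pos - 1L + ref_len
  color <- ifelse(tab$prioritized, "200,0,0",
                  ifelse(tab$is_eqtl, "230,130,0",
                         ifelse(nzchar(tab$regulatory), "0,80,200",
                                "120,120,120")))
  lines <- c(
    sprintf('track name="%s" description="high-LD proxies with cis-eQTL and regulatory annotation" itemRgb="On"',
            name),
    paste(tab$chrom, start0, end, tab$vid, pmin(round(1000 * tab$r2), 1000),
          ".", start0, end, color, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
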