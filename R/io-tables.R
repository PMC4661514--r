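#' Load a sample-to-population panel
#'
#' @param path TSV with header columns `sample`, `population` and optionally
#'   `super_population`.
#' @return A `data.frame` of class `population_panel`.
#' @export
load_panel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population")
  if (!all(need %in% names(tab)))
    stop2("panel file must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample))
    stop2("duplicate sample IDs in panel: %s",
          paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  class(tab) <- c("population_panel", "data.frame")
  tab
}

#' Samples belonging to one or more panel populations
#'
#' @param panel A panel `data.frame` from [load_panel()] (or any data frame
#'   with `sample` and `population` columns).
#' @param population Population label(s), super-population label(s) when the
#'   panel has a `super_population` column, or `"ALL"`.
#' @return Character vector of sample IDs.
#' @export
panel_samples <- function(panel, population = "ALL") {
  if (identical(population, "ALL")) return(panel$sample)
  hit <- panel$population %in% population
  if (!is.null(panel$super_population))
    hit <- hit | panel$super_population %in% population
  if (!any(hit))
    stop2("population '%s' not found in panel",
          paste(population, collapse = ","))
  panel$sample[hit]
}

#' Load an expression matrix and its probe-to-gene map
#'
#' The expression file is a TSV whose header names the samples and whose
#' first column holds probe IDs; the probe map is a TSV with columns
#' `probe` and `gene`. Probes absent from the map are dropped with a
#' warning, since they cannot be placed in cis to any gene.
#'
#' @param path Expression TSV path.
#' @param probe2gene_path Probe map TSV path.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (probes x samples numeric matrix), `samples`, `probes` and `probe2gene`
#'   (named character vector, probe -> gene).
#' @export
load_expression <- function(path, probe2gene_path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  probes <- as.character(tab[[1]])
  if (anyDuplicated(probes))
    stop2("duplicate probe IDs in expression matrix: %s",
          paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- rowSums(is.na(vals) & !is.na(as.matrix(tab[, -1, drop = FALSE]))) > 0
  if (any(bad))
    stop2("unparsable expression values in probe row(s): %s",
          paste(probes[bad], collapse = ", "))
  rownames(vals) <- probes

  map <- read.delim(probe2gene_path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(map)))
    stop2("probe map must have columns: probe, gene")
  probe2gene <- setNames(as.character(map$gene), as.character(map$probe))

  unmapped <- setdiff(probes, names(probe2gene))
  if (length(unmapped) > 0) {
    warn2("%d probe(s) absent from probe map; excluded: %s",
          length(unmapped), paste(utils::head(unmapped, 5), collapse = ", "))
    vals <- vals[setdiff(probes, unmapped), , drop = FALSE]
  }
  expression_matrix(vals, probe2gene)
}

#' Construct an expression matrix
#'
#' @param values Probes x samples numeric matrix with dimnames.
#' @param probe2gene Named character vector mapping probe IDs to gene IDs.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe2gene) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  probe2gene <- probe2gene[rownames(values)]
  structure(list(values = values, probes = rownames(values),
                 samples = colnames(values),
                 probe2gene = probe2gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%d genes)\n",
              length(x$probes), length(x$samples),
              length(unique(x$probe2gene))))
  invisible(x)
}

#' Load a GWAS catalog table
#'
#' @param path TSV with columns `rsid` and `trait`; a SNP may appear on
#'   several rows, one per associated trait.
#' @return `data.frame` with columns `rsid`, `trait` (deduplicated pairs).
#' @export
load_gwas_catalog <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rsid", "trait") %in% names(tab)))
    stop2("GWAS catalog must have columns: rsid, trait")
  unique(tab[, c("rsid", "trait")])
}
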