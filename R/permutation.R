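# LD-preserving permutation null: expression sample labels are shuffled
# while genotypes stay untouched, so only the phenotype-genotype link is
# broken and every LD relationship between variants is preserved exactly.

#' Permute expression sample labels
#'
#' Applies one global permutation of the sample labels jointly to all
#' probes, preserving the expression covariance structure across probes.
#'
#' @param em An [expression_matrix()].
#' @param seed Integer seed; the same seed always yields the same
#'   permutation.
#' @return A permuted `expression_matrix` (same dimnames, values moved
#'   between samples).
#' @export
permute_expression <- function(em, seed) {
  n <- length(em$samples)
  if (n < 2) stop2("need at least 2 samples to permute")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  vals <- em$values[, perm, drop = FALSE]
  colnames(vals) <- em$samples
  expression_matrix(vals, em$probe2gene)
}

#' Generate the cis-eQTL permutation null
#'
#' Reruns the full cis scan on `n_perm` phenotype permutations, pooling the
#' "fake cis-eQTLs" (records with `min_p < cutoff` under the null). As in
#' the real analysis the minimum five-model p-value is the statistic; with
#' `reduce = "variant"` (default) each variant keeps its best record across
#' probes before pooling, with `reduce = "pair"` all passing variant-probe
#' records enter the pool.
#'
#' @inheritParams cis_scan
#' @param n_perm Number of permutations (>= 1; the reference analysis used
#'   100).
#' @param seed Base seed; permutation `k` uses the deterministic substream
#'   seed `seed + k`.
#' @param cutoff Null cutoff (default `1e-4`).
#' @param reduce `"variant"` or `"pair"` (see above).
#' @param per_probe If `TRUE`, each probe is shuffled independently instead
#'   of one joint sample-label shuffle (an alternative, weaker null that
#'   breaks the expression covariance across probes).
#' @return A list of class `permutation_run`: `seed`, `n_perm`, `cutoff`,
#'   `fake_records` (pooled record table with a `perm` column) and
#'   `per_perm_counts` (`data.frame` perm, n_indel, n_snp).
#' @export
run_null <- function(gm, em, genes, panel = NULL, population = "ALL",
                     window = 200000L, cutoff = 1e-4, n_perm = 100L,
                     seed = 1L, anchor = c("span", "tss"),
                     reduce = c("variant", "pair"), per_probe = FALSE,
                     min_samples = 10L) {
  anchor <- match.arg(anchor); reduce <- match.arg(reduce)
  if (!is_count(n_perm) || n_perm < 1) stop2("'n_perm' must be a count >= 1")
  fake <- vector("list", n_perm)
  counts <- data.frame(perm = seq_len(n_perm), n_indel = 0L, n_snp = 0L)
  for (k in seq_len(n_perm)) {
    em_k <- if (per_probe) permute_per_probe(em, seed + k)
            else permute_expression(em, seed + k)
    rec <- cis_scan(gm, em_k, genes, panel, population, window, cutoff,
                    anchor, min_samples)
    if (reduce == "variant" && nrow(rec) > 0) {
      ord <- order(rec$vid, rec$min_p, rec$probe)
      rec <- rec[ord, , drop = FALSE]
      rec <- rec[!duplicated(rec$vid), , drop = FALSE]
    }
    counts$n_indel[k] <- sum(rec$vclass == "INDEL")
    counts$n_snp[k] <- sum(rec$vclass == "SNP")
    if (nrow(rec) > 0) rec$perm <- k
    fake[[k]] <- rec
  }
  fake_records <- do.call(rbind, fake[vapply(fake, nrow, 1L) > 0])
  if (is.null(fake_records)) {
    fake_records <- empty_records(); fake_records$perm <- integer(0)
  }
  rownames(fake_records) <- NULL
  structure(list(seed = seed, n_perm = n_perm, cutoff = cutoff,
                 reduce = reduce, fake_records = fake_records,
                 per_perm_counts = counts),
            class = "permutation_run")
}

permute_per_probe <- function(em, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  vals <- t(apply(em$values, 1, sample))
  dimnames(vals) <- dimnames(em$values)
  expression_matrix(vals, em$probe2gene)
}

#' @export
print.permutation_run <- function(x, ...) {
  cat(sprintf(
    "permutation_run: %d permutations at cutoff %g (%s-reduced)\n",
    x$n_perm, x$cutoff, x$reduce))
  cat(sprintf("fake cis-eQTLs per permutation: indel %.1f +/- %.1f, SNP %.1f +/- %.1f\n",
              mean(x$per_perm_counts$n_indel), sd(x$per_perm_counts$n_indel),
              mean(x$per_perm_counts$n_snp), sd(x$per_perm_counts$n_snp)))
  invisible(x)
}
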