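# Pairwise linkage disequilibrium. With A/a the two alleles at the first
# site and B/b at the second (allele 1 = alt), and p_AB .. p_ab the four
# haplotype frequencies:
#   D    = p_AB - p_A * p_B
#   r^2  = D^2 / (p_A (1 - p_A) p_B (1 - p_B))
#   D'   = |D| / D_max,
#   D_max = min(p_A (1 - p_B), (1 - p_A) p_B)         if D > 0
#           min(p_A p_B, (1 - p_A)(1 - p_B))          if D < 0
# Phased data is counted directly; unphased genotypes go through an EM that
# resolves the double-heterozygote phase ambiguity.

ld_from_freqs <- function(pAB, pAb, paB, pab, n_hap, method,
                          converged = TRUE, ambiguous = FALSE,
                          A = NA_character_, B = NA_character_) {
  pA <- pAB + pAb; pB <- pAB + paB
  if (anyNA(c(pAB, pAb, paB, pab)) || pA <= 0 || pA >= 1 ||
      pB <= 0 || pB >= 1) {
    r2 <- dprime <- D <- NA_real_
  } else {
    D <- pAB - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    dprime <- if (D == 0) 0 else abs(D) / dmax
  }
  structure(list(A = A, B = B, r2 = r2, dprime = dprime, D = D,
                 hap_freqs = c(p_AB = pAB, p_Ab = pAb, p_aB = paB, p_ab = pab),
                 n_hap = n_hap, method = method, converged = converged,
                 ambiguous = ambiguous),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("ld_result [%s]%s: r2 = %s, D' = %s (n_hap = %d)\n",
              x$method,
              if (!is.na(x$A)) sprintf(" %s x %s", x$A, x$B) else "",
              format(x$r2, digits = 4), format(x$dprime, digits = 4),
              x$n_hap))
  invisible(x)
}

#' LD from phased haplotypes
#'
#' Direct haplotype counting; haplotype slots missing at either site are
#' dropped. Monomorphic sites give `r2 = D' = NA`.
#'
#' @param hapA,hapB Binary allele vectors (one entry per haplotype,
#'   1 = alt), equal length.
#' @return An `ld_result` list: `r2`, `dprime` (absolute, in `[0,1]`), `D`,
#'   `hap_freqs` (p_AB, p_Ab, p_aB, p_ab), `n_hap`, `method = "phased"`.
#' @export
ld_phased <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  ok <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[ok]; b <- hapB[ok]
  n <- length(a)
  if (n == 0) return(ld_from_freqs(NA, NA, NA, NA, 0L, "phased"))
  pAB <- sum(a == 1 & b == 1) / n
  pAb <- sum(a == 1 & b == 0) / n
  paB <- sum(a == 0 & b == 1) / n
  pab <- sum(a == 0 & b == 0) / n
  ld_from_freqs(pAB, pAb, paB, pab, n, "phased")
}

#' LD from unphased genotypes by EM haplotype-frequency estimation
#'
#' Individuals missing either genotype are dropped. All genotype
#' combinations except the double heterozygote determine their two
#' haplotypes; the EM iterates the expected split of double heterozygotes
#' between the cis (AB/ab) and trans (Ab/aB) configurations, starting from
#' linkage equilibrium, until the largest absolute frequency change is
#' below `tol` or `max_iter` is reached (then flagged unconverged).
#' A sample consisting only of double heterozygotes has two symmetric
#' likelihood optima and is flagged `ambiguous`.
#'
#' @param gA,gB Genotype dosage vectors in `{0,1,2}`.
#' @param tol Convergence threshold on haplotype frequencies (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An `ld_result` with `method = "EM"`.
#' @export
ld_em <- function(gA, gB, tol = 1e-8, max_iter = 1000L) {
  stopifnot(length(gA) == length(gB))
  ok <- !is.na(gA) & !is.na(gB)
  a <- gA[ok]; b <- gB[ok]
  n <- length(a)
  if (n == 0) return(ld_from_freqs(NA, NA, NA, NA, 0L, "EM"))
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[a[i] + 1, b[i] + 1] <- cnt[a[i] + 1, b[i] + 1] + 1
  nDH <- cnt[2, 2]
  # fixed haplotype contributions from unambiguous genotypes
  c11 <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  c10 <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  c01 <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]
  c00 <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  pA <- (2 * sum(cnt[3, ]) + sum(cnt[2, ])) / (2 * n)
  pB <- (2 * sum(cnt[, 3]) + sum(cnt[, 2])) / (2 * n)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(ld_from_freqs(NA, NA, NA, NA, 2L * n, "EM"))
  # initialize at linkage equilibrium
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    f <- if (denom > 0) p[1] * p[4] / denom else 0.5
    new <- c(c11 + f * nDH, c10 + (1 - f) * nDH,
             c01 + (1 - f) * nDH, c00 + f * nDH) / (2 * n)
    if (max(abs(new - p)) < tol) { p <- new; converged <- TRUE; break }
    p <- new
  }
  ambiguous <- nDH == n && n > 0
  ld_from_freqs(p[1], p[2], p[3], p[4], 2L * n, "EM",
                converged = converged, ambiguous = ambiguous)
}

#' LD between two variants of a genotype matrix
#'
#' Uses phased counting when the matrix is phased, EM otherwise.
#'
#' @param gm A [genotype_matrix()].
#' @param vidA,vidB Variant IDs.
#' @param ... Passed to [ld_em()] for unphased input.
#' @return An `ld_result`.
#' @export
ld_pair <- function(gm, vidA, vidB, ...) {
  ia <- match(vidA, gm$variants$vid); ib <- match(vidB, gm$variants$vid)
  if (is.na(ia) || is.na(ib))
    stop2("variant not in genotype matrix: %s",
          paste(c(vidA, vidB)[c(is.na(ia), is.na(ib))], collapse = ", "))
  res <- if (gm$phased) ld_phased(gm$haplotypes[ia, ], gm$haplotypes[ib, ])
         else ld_em(gm$codes[ia, ], gm$codes[ib, ], ...)
  res$A <- vidA; res$B <- vidB
  res
}

#' Search high-LD proxies of a query variant
#'
#' Scans all variants within the proxy window around the query position and
#' reports those with `r2 >= r2_min`, sorted by descending r2; the query
#' itself heads the list with `r2 = 1`. The window is the total span: a
#' 1000 kb window reaches 500 kb to each side (`half_window = FALSE`
#' interprets `window` as the per-side distance instead).
#'
#' @param query Variant ID present in `gm`.
#' @param gm A [genotype_matrix()] (restrict to a population first with
#'   [subset_samples()], or pool populations by passing the pooled matrix).
#' @param window Total window span in bp (default 1e6).
#' @param r2_min Minimum r2 to report (default 0.7).
#' @param half_window If `TRUE` (default) `window` is the total span.
#' @return `data.frame`: `vid`, `chrom`, `pos`, `vclass`, `r2`, `dprime`,
#'   `n_hap`, `method`.
#' @export
proxy_search <- function(query, gm, window = 1e6, r2_min = 0.7,
                         half_window = TRUE) {
  qi <- match(query, gm$variants$vid)
  if (is.na(qi))
    stop2("query variant '%s' not present in the genotype panel", query)
  check_fraction(r2_min, "r2_min")
  v <- gm$variants
  reach <- if (half_window) window / 2 else window
  cand <- which(v$chrom == v$chrom[qi] & abs(v$pos - v$pos[qi]) <= reach)
  res <- lapply(cand, function(i) {
    r <- if (gm$phased) ld_phased(gm$haplotypes[qi, ], gm$haplotypes[i, ])
         else ld_em(gm$codes[qi, ], gm$codes[i, ])
    data.frame(vid = v$vid[i], chrom = v$chrom[i], pos = v$pos[i],
               vclass = v$vclass[i], r2 = r$r2, dprime = r$dprime,
               n_hap = r$n_hap, method = r$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[!is.na(out$r2) & out$r2 >= r2_min, , drop = FALSE]
  out <- out[order(-out$r2, out$vid != query, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export genotypes in linkage PED/INFO format for external LD plotting
#'
#' Writes the two files expected by classical haplotype viewers: a
#' pre-makeped linkage PED (family/individual columns then one allele pair
#' per marker, 1 = ref, 2 = alt, 0 0 = missing) and a marker INFO file
#' (marker name, position).
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.info`.
#' @return Named character vector of the two paths, invisibly.
#' @export
export_haploview <- function(gm, prefix) {
  n <- length(gm$samples)
  if (gm$phased) {
    a1 <- gm$haplotypes[, seq(1, 2 * n, 2), drop = FALSE] + 1L
    a2 <- gm$haplotypes[, seq(2, 2 * n, 2), drop = FALSE] + 1L
  } else {
    a1 <- ifelse(gm$codes >= 1, 2L, 1L)
    a2 <- ifelse(gm$codes == 2, 2L, 1L)
  }
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  geno <- matrix(paste(a1, a2), nrow = nrow(gm$codes))
  ped <- cbind(gm$samples, gm$samples, 0, 0, 0, 0, t(geno))
  ped_path <- paste0(prefix, ".ped"); info_path <- paste0(prefix, ".info")
  write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  write.table(gm$variants[, c("vid", "pos")], info_path, quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(c(ped = ped_path, info = info_path))
}
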