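# Five-model genotype-expression association engine.
#
# All five classical single-variant models for a quantitative trait are
# ordinary least-squares fits on recoded alt-allele dosages g in {0,1,2}:
#   ADD       y ~ g                    t-test on the slope, df = n - 2
#   DOM       y ~ [g >= 1]             t-test, df = n - 2
#   REC       y ~ [g == 2]             t-test, df = n - 2
#   GENO_2DF  y ~ g + het              joint F-test of both slopes, df (2, n-3)
#   DOMDEV    y ~ g + het              t-test on the het coefficient, df n - 3
# where het = [g == 1]. The eQTL statistic is the minimum p-value across the
# estimable models ("min-P"), with ties broken in the fixed order
# ADD < GENO_2DF < DOMDEV < DOM < REC so results are reproducible.

MODEL_ORDER <- c("ADD", "GENO_2DF", "DOMDEV", "DOM", "REC")

#' Recode a genotype dosage under a genetic model
#'
#' @param g Genotype dosages in `{0, 1, 2}` (non-missing).
#' @param model One of `"ADD"`, `"DOM"`, `"REC"`, `"GENO_2DF"`, `"DOMDEV"`.
#' @return For the single-predictor models a numeric vector; for
#'   `GENO_2DF`/`DOMDEV` a two-column matrix `(g, het)`.
#' @examples
#' encode_genotype(c(0, 1, 2), "DOM")   # 0 1 1
#' encode_genotype(c(0, 1, 2), "REC")   # 0 0 1
#' @export
encode_genotype <- function(g, model = MODEL_ORDER) {
  model <- match.arg(model)
  switch(model,
         ADD = as.numeric(g),
         DOM = as.numeric(g >= 1),
         REC = as.numeric(g == 2),
         GENO_2DF = ,
         DOMDEV = cbind(g = as.numeric(g), het = as.numeric(g == 1)))
}

#' Fit one genetic association model
#'
#' Pairs with a missing genotype or expression value are dropped (pairwise
#' deletion). Models whose design is degenerate return `p = NA`: a constant
#' predictor for ADD/DOM/REC, and a rank-deficient `(g, het)` design — e.g.
#' no heterozygotes — for GENO_2DF/DOMDEV.
#'
#' @param y Expression vector.
#' @param g Genotype dosage vector aligned with `y`.
#' @param model Model label.
#' @return A `data.frame` row with `model`, `beta` (NA for GENO_2DF),
#'   `stat`, `df1`, `df2`, `p`, `n_used`.
#' @export
fit_model <- function(y, g, model = MODEL_ORDER) {
  model <- match.arg(model)
  f <- fit_five(y, g)
  data.frame(model = model, beta = f$beta[[model]], stat = f$stat[[model]],
             df1 = f$df1[[model]], df2 = f$df2[[model]], p = f$p[[model]],
             n_used = f$n_used, stringsAsFactors = FALSE)
}

# Closed-form engine computing all five models at once (hot path of the
# cis scan and the permutation null). Returns named lists of per-model
# beta/stat/df/p plus n_used.
fit_five <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  out <- list(
    beta = c(ADD = NA_real_, GENO_2DF = NA_real_, DOMDEV = NA_real_,
             DOM = NA_real_, REC = NA_real_),
    stat = c(ADD = NA_real_, GENO_2DF = NA_real_, DOMDEV = NA_real_,
             DOM = NA_real_, REC = NA_real_),
    df1 = c(ADD = NA_real_, GENO_2DF = NA_real_, DOMDEV = NA_real_,
            DOM = NA_real_, REC = NA_real_),
    df2 = c(ADD = NA_real_, GENO_2DF = NA_real_, DOMDEV = NA_real_,
            DOM = NA_real_, REC = NA_real_),
    p = c(ADD = NA_real_, GENO_2DF = NA_real_, DOMDEV = NA_real_,
          DOM = NA_real_, REC = NA_real_),
    n_used = n)
  if (n < 3) return(out)

  my <- mean(y); yc <- y - my; syy <- sum(yc * yc)

  simple <- function(x, df) {
    mx <- mean(x); xc <- x - mx
    sxx <- sum(xc * xc)
    if (sxx <= 0) return(c(NA_real_, NA_real_, NA_real_))
    sxy <- sum(xc * yc)
    b <- sxy / sxx
    sse <- max(syy - b * sxy, 0)
    if (df < 1) return(c(b, NA_real_, NA_real_))
    se2 <- sse / df / sxx
    t <- if (se2 > 0) b / sqrt(se2) else sign(b) * Inf
    c(b, t, 2 * pt(-abs(t), df))
  }

  for (m in c("ADD", "DOM", "REC")) {
    r <- simple(encode_genotype(g, m), n - 2)
    out$beta[[m]] <- r[1]; out$stat[[m]] <- r[2]
    out$df1[[m]] <- n - 2; out$df2[[m]] <- NA_real_; out$p[[m]] <- r[3]
  }

  # joint (g, het) fit for GENO_2DF and DOMDEV
  if (n >= 4) {
    h <- as.numeric(g == 1)
    gc <- g - mean(g); hc <- h - mean(h)
    sgg <- sum(gc * gc); shh <- sum(hc * hc); sgh <- sum(gc * hc)
    det <- sgg * shh - sgh * sgh
    if (sgg > 0 && shh > 0 && det > 1e-10 * sgg * shh) {
      sgy <- sum(gc * yc); shy <- sum(hc * yc)
      b1 <- (shh * sgy - sgh * shy) / det
      b2 <- (sgg * shy - sgh * sgy) / det
      sse <- max(syy - b1 * sgy - b2 * shy, 0)
      df <- n - 3
      sigma2 <- sse / df
      ssr <- syy - sse
      Fst <- if (sigma2 > 0) (ssr / 2) / sigma2 else Inf
      out$beta[["GENO_2DF"]] <- NA_real_
      out$stat[["GENO_2DF"]] <- Fst
      out$df1[["GENO_2DF"]] <- 2; out$df2[["GENO_2DF"]] <- df
      out$p[["GENO_2DF"]] <- pf(Fst, 2, df, lower.tail = FALSE)
      se2 <- sigma2 * sgg / det
      t2 <- if (se2 > 0) b2 / sqrt(se2) else sign(b2) * Inf
      out$beta[["DOMDEV"]] <- b2
      out$stat[["DOMDEV"]] <- t2
      out$df1[["DOMDEV"]] <- df; out$df2[["DOMDEV"]] <- NA_real_
      out$p[["DOMDEV"]] <- 2 * pt(-abs(t2), df)
    }
  }
  out
}

#' Five-model minimum-P association result
#'
#' Fits all five models and designates the smallest non-NA p-value as the
#' cis-eQTL statistic (min-P), with ties broken by the fixed model order
#' ADD, GENO_2DF, DOMDEV, DOM, REC.
#'
#' @param variant Variant ID (carried through to the result).
#' @param probe Probe ID.
#' @param population Population label.
#' @param y,g Expression and genotype vectors aligned on individuals.
#' @return A list of class `association_result` with elements `variant`,
#'   `probe`, `population`, `fits` (five-row data frame), `min_p`,
#'   `best_model`, `n_used` and `estimable`. When all five models are
#'   inestimable (e.g. a monomorphic genotype) `estimable` is `FALSE` and
#'   `min_p` is `NA`.
#' @export
min_p_result <- function(variant, probe, population, y, g) {
  f <- fit_five(y, g)
  fits <- data.frame(model = MODEL_ORDER, beta = f$beta[MODEL_ORDER],
                     stat = f$stat[MODEL_ORDER], df1 = f$df1[MODEL_ORDER],
                     df2 = f$df2[MODEL_ORDER], p = f$p[MODEL_ORDER],
                     n_used = f$n_used, row.names = NULL,
                     stringsAsFactors = FALSE)
  p <- f$p[MODEL_ORDER]
  est <- any(!is.na(p))
  best <- if (est) MODEL_ORDER[which.min(p)] else NA_character_
  structure(list(variant = variant, probe = probe, population = population,
                 fits = fits,
                 min_p = if (est) min(p, na.rm = TRUE) else NA_real_,
                 best_model = best, n_used = f$n_used, estimable = est),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result %s ~ %s [%s]: min_p = %s (%s), n = %d\n",
              x$probe, x$variant, x$population,
              format(x$min_p, digits = 3), x$best_model, x$n_used))
  print(x$fits, row.names = FALSE)
  invisible(x)
}
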