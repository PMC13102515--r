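#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the usual t-test on n - 2 degrees of freedom,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. Constant input yields a flagged
#' missing result rather than an error so callers can drop the pair.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `r` and `p` (both `NA` when either vector is
#'   constant).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the
#' chance of drawing at least `k` annotated genes when `n` genes are drawn
#' from a universe of `N` containing `K` annotated ones. This is the
#' standard "Fisher test" for gene-set enrichment.
#'
#' @param k annotated genes in the drawn set.
#' @param n drawn set size.
#' @param K annotated genes in the universe.
#' @param N universe size.
#' @return the p-value.
#' @export
fisher_enrichment <- function(k, n, K, N) {
  ok <- k >= 0 && n >= 0 && K >= 0 && N >= 0 && k <= n && n <= N && k <= K &&
    K <= N
  if (!ok) stopf("inconsistent counts: k=%s n=%s K=%s N=%s", k, n, K, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value; used for control-vs-knockdown
#' comparisons.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stopf("each group needs at least 2 observations")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Term enrichment of a gene set
#'
#' One hypergeometric over-representation test per term with at least one
#' universe member, BH-adjusted across all tested terms.
#'
#' @param gene_set character vector of genes (subset of `universe`).
#' @param annotation gene annotation data.frame (see
#'   [read_gene_annotation()]); terms are taken from its `term_ids`
#'   column.
#' @param universe character vector of background genes.
#' @return data.frame with columns `term_id`, `k`, `n`, `K`, `N`, `p`,
#'   `q`, sorted by `q` then `p`; empty (with a warning) for an empty gene
#'   set.
#' @export
term_enrichment <- function(gene_set, annotation, universe) {
  if (!length(universe)) stopf("empty universe")
  if (!all(gene_set %in% universe)) stopf("gene_set must be a subset of universe")
  empty <- data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (!length(gene_set)) {
    warnf("empty gene set: no enrichment computed")
    return(empty)
  }
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- strsplit(ann$term_ids, ";", fixed = TRUE)
  long <- data.frame(
    gene_id = rep(ann$gene_id, lengths(terms)),
    term_id = unlist(terms),
    stringsAsFactors = FALSE)
  long <- long[long$term_id != "", , drop = FALSE]
  if (!nrow(long)) return(empty)
  N <- length(universe)
  n <- length(gene_set)
  Ks <- table(long$term_id)
  ks <- table(long$term_id[long$gene_id %in% gene_set])
  term_ids <- names(Ks)
  k <- as.integer(ifelse(term_ids %in% names(ks), ks[term_ids], 0L))
  K <- as.integer(Ks)
  p <- mapply(fisher_enrichment, k = k, n = n, K = K, N = N)
  out <- data.frame(term_id = term_ids, k = k, n = n, K = K, N = N, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test using mid-ranks for ties. When both groups have
#' at most `exact_max` observations the permutation null is enumerated
#' exhaustively (every reassignment of the pooled mid-ranks), otherwise
#' the normal approximation with the tie-corrected variance is used.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest group size for which the exact null is
#'   enumerated.
#' @return list with `W` (rank sum of `x` minus its minimum, the usual
#'   Mann-Whitney U), `p`, and `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    mu <- n1 * (n1 + n2 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(W = w - n1 * (n1 + 1) / 2, p = 1,
                                 method = "normal"))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = w - n1 * (n1 + 1) / 2, p = min(p, 1), method = method)
}
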