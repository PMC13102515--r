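# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the package's vectorized code paths.

# score every window on both strands by direct per-base summation
brute_scan <- function(seq, pwm, rel_threshold, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  pc <- pwm$pseudocount
  sc <- log2((pwm$probs + pc * background) / ((1 + pc) * background))
  smax <- sum(apply(sc, 2, max)); smin <- sum(apply(sc, 2, min))
  w <- pwm$width
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- data.frame(position = integer(0), strand = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  if (L < w) return(out)
  rc <- function(x) rev(chartr("ACGTN", "TGCAN", x))
  for (pos in 0:(L - w)) {
    win <- chars[(pos + 1):(pos + w)]
    if (any(win == "N")) next
    s_f <- sum(sc[cbind(match(win, bases), seq_len(w))])
    s_r <- sum(sc[cbind(match(rc(win), bases), seq_len(w))])
    rel_f <- (s_f - smin) / (smax - smin)
    rel_r <- (s_r - smin) / (smax - smin)
    if (rel_f >= rel_threshold) {
      out <- rbind(out, data.frame(position = pos, strand = "+",
                                   score = rel_f, stringsAsFactors = FALSE))
    }
    if (rel_r >= rel_threshold) {
      out <- rbind(out, data.frame(position = pos, strand = "-",
                                   score = rel_r, stringsAsFactors = FALSE))
    }
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

random_pwm <- function(w) {
  probs <- matrix(stats::rgamma(4 * w, 1), 4, w)
  probs <- sweep(probs, 2, colSums(probs), "/")
  new_pwm("rand", probs)
}

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
               prob = c(.24, .24, .24, .24, .04)), collapse = "")
}

# exhaustive-draw hypergeometric tail: enumerate every n-subset of 1..N
enum_fisher <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# exhaustive two-sided rank-sum permutation p (mid-ranks)
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (length(r) + 1) / 2
  sums <- colSums(matrix(r[utils::combn(length(r), n1)], nrow = n1))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-12)
}

# minimal ModuleAssignment carrying planted modules as the assignment
truth_modules <- function(truth) {
  structure(list(module_of = truth$module_of,
                 K = length(unique(truth$module_of)),
                 centroids = NULL, inertia = NA_real_, seed = NA_integer_),
            class = "ModuleAssignment")
}

# small count matrix from a dense integer matrix
cm <- function(m) {
  count_matrix(m, sprintf("S%02d", seq_len(nrow(m))),
               sprintf("G%02d", seq_len(ncol(m))))
}
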