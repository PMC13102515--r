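BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param name TF-family key.
#' @param probs 4 x width numeric matrix of base probabilities, rows in
#'   A, C, G, T order; columns must each sum to 1 within 1e-6.
#' @param pseudocount small positive smoothing constant used when taking
#'   log-odds.
#' @return an object of class `PWM`.
#' @export
new_pwm <- function(name, probs, pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stopf("PWM must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1L) stopf("PWM '%s' has width 0", name)
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    stopf("PWM '%s': column probabilities must sum to 1", name)
  }
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  rownames(probs) <- BASES
  structure(list(name = name, probs = probs, width = ncol(probs),
                 pseudocount = pseudocount), class = "PWM")
}

#' Consensus sequence of a PWM
#'
#' The highest-probability base at each column; ties broken by A < C < G < T.
#' @param pwm a [new_pwm()] object.
#' @return a character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Log-odds score matrix of a PWM
#'
#' Smooths the probability matrix with `pseudocount` mass of the
#' background and scores each base against the background:
#' `entry(b, i) = log2((p[b,i] + pc * bg[b]) / ((1 + pc) * bg[b]))`.
#' Also returns the analytic maximum and minimum achievable window scores,
#' which [scan_sequence()] uses to place raw scores on a relative 0-1
#' scale.
#'
#' @param pwm a [new_pwm()] object.
#' @param background base probabilities (A, C, G, T); must be positive and
#'   sum to 1. Default uniform.
#' @return list with `scores` (4 x width), `max_score`, `min_score`.
#' @export
pwm_log_odds <- function(pwm, background = rep(0.25, 4)) {
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stopf("background must be 4 positive probabilities summing to 1")
  }
  pc <- pwm$pseudocount
  sc <- log2((pwm$probs + pc * background) / ((1 + pc) * background))
  rownames(sc) <- BASES
  list(scores = sc,
       max_score = sum(apply(sc, 2, max)),
       min_score = sum(apply(sc, 2, min)))
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar over A, C, G, T, N.
#' @return character scalar.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Scan one sequence with a PWM
#'
#' Scores every window of the motif width on the forward strand and on the
#' reverse complement. Raw window scores are rescaled to
#' `(S - S_min) / (S_max - S_min)` and windows at or above
#' `rel_threshold` are reported. Reverse-strand hits are reported at the
#' forward-strand offset of the window's leftmost base. Windows containing
#' `N` are skipped.
#'
#' @param seq promoter sequence (A, C, G, T, N).
#' @param pwm a [new_pwm()] object.
#' @param rel_threshold relative score cutoff in (0, 1].
#' @param background background base probabilities for the log-odds.
#' @return data.frame with columns `position` (0-based), `strand`
#'   (`"+"`/`"-"`), `score` (relative); empty when the sequence is shorter
#'   than the motif.
#' @export
scan_sequence <- function(seq, pwm, rel_threshold = 0.85,
                          background = rep(0.25, 4)) {
  if (rel_threshold <= 0 || rel_threshold > 1) {
    stopf("rel_threshold must be in (0, 1]")
  }
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  w <- pwm$width
  L <- nchar(seq)
  if (L < w) return(empty)
  lo <- pwm_log_odds(pwm, background)
  span <- lo$max_score - lo$min_score
  codes <- match(strsplit(seq, "")[[1]], BASES)   # N -> NA
  n_win <- L - w + 1L
  score_strand <- function(sc) {
    s <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (i in seq_len(w)) {
      b <- codes[i:(i + n_win - 1L)]
      ok <- ok & !is.na(b)
      bi <- ifelse(is.na(b), 1L, b)
      s <- s + sc[cbind(bi, i)]
    }
    s[!ok] <- NA_real_
    s
  }
  fwd <- score_strand(lo$scores)
  # reverse strand: score the reverse-complemented PWM on the forward
  # sequence so positions stay in forward coordinates
  sc_rc <- lo$scores[4:1, w:1, drop = FALSE]
  rev_ <- score_strand(sc_rc)
  rel_f <- (fwd - lo$min_score) / span
  rel_r <- (rev_ - lo$min_score) / span
  hits_f <- which(!is.na(rel_f) & rel_f >= rel_threshold)
  hits_r <- which(!is.na(rel_r) & rel_r >= rel_threshold)
  out <- data.frame(
    position = c(hits_f, hits_r) - 1L,
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(rel_f[hits_f], rel_r[hits_r]),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Scan a promoter set against a motif library
#'
#' @param promoters named character vector of promoter sequences.
#' @param library named list of PWMs (names key TF families).
#' @param rel_threshold relative score cutoff in (0, 1].
#' @param background background base probabilities.
#' @return a `MotifHitTable`: data.frame with columns `gene_id`, `family`,
#'   `position`, `strand`, `score`, sorted by gene, family, position.
#' @export
scan_promoters <- function(promoters, library, rel_threshold = 0.85,
                           background = rep(0.25, 4)) {
  if (!length(library)) stopf("empty motif library")
  rows <- list()
  for (gene in names(promoters)) {
    for (fam in names(library)) {
      h <- scan_sequence(promoters[[gene]], library[[fam]], rel_threshold,
                         background)
      if (nrow(h)) {
        h$gene_id <- gene
        h$family <- fam
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), family = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)[, c("gene_id", "family", "position", "strand",
                                  "score")]
  out <- out[order(out$gene_id, out$family, out$position, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
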