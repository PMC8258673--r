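revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         vapply(sequence, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

pwm_log_odds <- function(matrix, background = rep(0.25, 4)) {
  log2(matrix) - log2(background)
}

#' Exact tail probability of a PWM log-odds score
#'
#' Computes P(score(X) >= s) for a random width-mer X drawn from the
#' background model, by convolving the per-column score distributions. For
#' widths up to 10 the convolution keeps every achievable floating-point
#' partial sum (equivalent to full enumeration of all 4^width words); wider
#' matrices use an integer score lattice at fine granularity, rounded
#' conservatively so the returned p-value never understates the tail.
#'
#' @param matrix 4 x width probability matrix (rows A, C, G, T).
#' @param score Observed log-odds score (base-2, same background).
#' @param background Background nucleotide probabilities (A, C, G, T).
#' @return The exact tail probability.
#' @export
pwm_exact_pvalue <- function(matrix, score, background = rep(0.25, 4)) {
  w <- ncol(matrix)
  lod <- pwm_log_odds(matrix, background)
  if (w <= 10L) {
    sums <- 0; probs <- 1
    for (cc in seq_len(w)) {
      sums <- as.vector(outer(sums, lod[, cc], "+"))
      probs <- as.vector(outer(probs, background, "*"))
    }
    return(sum(probs[sums >= score - 1e-9]))
  }
  # integer lattice convolution
  finite <- lod[is.finite(lod)]
  floor_val <- min(finite) - 1000
  lod[!is.finite(lod)] <- floor_val
  K <- 1e4
  li <- round(lod * K)
  offset <- apply(li, 2, min)
  span <- sum(apply(li, 2, max) - offset)
  dist <- c(1, rep(0, span))
  for (cc in seq_len(w)) {
    nd <- rep(0, length(dist))
    for (b in 1:4) {
      sft <- li[b, cc] - offset[cc]
      nd[(1 + sft):length(dist)] <-
        nd[(1 + sft):length(dist)] +
        background[b] * dist[seq_len(length(dist) - sft)]
    }
    dist <- nd
  }
  t_int <- floor(score * K) - sum(offset) - w  # per-column rounding slack
  if (t_int <= 0) return(1)
  if (t_int > span) return(0)
  sum(dist[(t_int + 1):length(dist)])
}

#' Scan a guide for the best complementary motif match
#'
#' Scans the reverse complement of the guide (tRF) sequence with the motif's
#' log-odds matrix (guide–target base pairing), reports the best-scoring
#' window and its exact background tail probability from
#' [pwm_exact_pvalue()], and maps the matched window back onto 5'->3' guide
#' coordinates.
#'
#' @param matrix 4 x width PWM probability matrix, or a `trf_pwm` object.
#' @param sequence Guide sequence (5'->3').
#' @param background Background nucleotide probabilities.
#' @param revcomp_scan Scan the reverse complement (default) or the sequence
#'   itself.
#' @return List with `position` (on the scanned strand), `score`, `p_value`
#'   and `trf_interval` (closed interval on the input sequence).
#' @export
pwm_match_pvalue <- function(matrix, sequence, background = rep(0.25, 4),
                             revcomp_scan = TRUE) {
  if (inherits(matrix, "trf_pwm")) matrix <- matrix$matrix
  w <- ncol(matrix)
  n <- nchar(sequence)
  if (w > n) {
    rlang::abort("motif wider than the scanned sequence",
                 class = "trf_bad_interval")
  }
  scanned <- if (revcomp_scan) revcomp(sequence) else sequence
  enc <- encode_seq(scanned)
  lod <- pwm_log_odds(matrix, background)
  m <- n - w + 1L
  idx <- outer(seq_len(m), 0:(w - 1L), "+")
  Wm <- matrix(enc[idx], nrow = m)
  sc <- rep(-Inf, m)
  ok <- !apply(is.na(Wm), 1, any)
  if (any(ok)) {
    col_idx <- rep(seq_len(w), each = sum(ok))
    sc[ok] <- rowSums(matrix(lod[cbind(as.vector(Wm[ok, , drop = FALSE]), col_idx)],
                             nrow = sum(ok)))
  }
  j <- which.max(sc)
  best <- sc[j]
  iv <- if (revcomp_scan) c(n - (j + w - 1L) + 1L, n - j + 1L) else c(j, j + w - 1L)
  list(position = as.integer(j), score = best,
       p_value = if (is.finite(best)) pwm_exact_pvalue(matrix, best, background) else 1,
       trf_interval = as.integer(iv))
}

#' Match a discovered motif back onto its guide
#'
#' Convenience wrapper around [pwm_match_pvalue()] that stores the matched
#' guide interval and match-back p-value on the `trf_pwm` object. The match
#' is reported as significant when the p-value passes
#' `thresholds$matchback_pvalue_max`.
#'
#' @param motif A `trf_pwm` object.
#' @param trf_sequence Guide sequence (5'->3').
#' @param trf_name Optional canonical name stored on the motif.
#' @param background Background nucleotide probabilities.
#' @param thresholds A [trf_thresholds()] record.
#' @return The motif with `trf_interval`, `matchback_pvalue` and
#'   `matchback_significant` fields set.
#' @export
match_back <- function(motif, trf_sequence, trf_name = NULL,
                       background = rep(0.25, 4),
                       thresholds = trf_thresholds()) {
  hit <- pwm_match_pvalue(motif$matrix, trf_sequence, background)
  motif$trf_interval <- hit$trf_interval
  motif$matchback_pvalue <- hit$p_value
  motif$matchback_score <- hit$score
  motif$matchback_significant <- hit$p_value < thresholds$matchback_pvalue_max
  if (!is.null(trf_name)) motif$trf_name <- trf_name
  motif
}
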