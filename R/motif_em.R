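BASES <- c("A", "C", "G", "T")

encode_seq <- function(s) match(strsplit(s, "")[[1]], BASES)

# window matrix (one row per window) over a list of integer-encoded sequences
window_matrix <- function(enc, width) {
  rows <- list(); seq_of <- list()
  for (i in seq_along(enc)) {
    v <- enc[[i]]
    m <- length(v) - width + 1L
    if (m < 1L) next
    idx <- outer(seq_len(m), 0:(width - 1L), "+")
    W <- matrix(v[idx], nrow = m)
    ok <- !apply(is.na(W), 1, any)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- W[ok, , drop = FALSE]
    seq_of[[length(seq_of) + 1L]] <- rep(i, sum(ok))
  }
  if (!length(rows)) return(NULL)
  seq_of <- unlist(seq_of)
  used <- sort(unique(seq_of))
  list(W = do.call(rbind, rows),
       seq_of = match(seq_of, used),  # contiguous ids
       used = used)
}

# indicator matrices making the EM inner loop a handful of BLAS products:
# M (4*width x n_win) one-hot of each window cell's (base, column);
# S (n_seq x n_win) one-hot of each window's parent sequence
em_design <- function(wm, width) {
  W <- wm$W; n_win <- nrow(W)
  n_seq <- max(wm$seq_of)
  M <- matrix(0, 4L * width, n_win)
  M[cbind(as.vector(W) + rep(4L * (seq_len(width) - 1L), each = n_win),
          rep(seq_len(n_win), width))] <- 1
  S <- matrix(0, n_seq, n_win)
  S[cbind(wm$seq_of, seq_len(n_win))] <- 1
  list(M = M, S = S)
}

# One ZOOPS (zero-or-one occurrence per sequence) EM run from a seeded start.
# Returns the fitted PWM, site posteriors and the log-likelihood-ratio score
# of the mixture against the background-only model.
zoops_em_run <- function(wm, weights, bg, width, seed_window, design,
                         max_iter = 50, tol = 1e-5, init_theta = NULL) {
  W <- wm$W; seq_of <- wm$seq_of
  n_win <- nrow(W)
  n_seq <- max(seq_of)
  m_i <- tabulate(seq_of, nbins = n_seq)
  u <- weights[wm$used]
  u_of <- u[seq_of]; m_of <- m_i[seq_of]
  M <- design$M; S <- design$S
  if (is.null(init_theta)) {
    theta <- matrix(0.1 / 3, nrow = 4, ncol = width, dimnames = list(BASES, NULL))
    theta[cbind(W[seed_window, ], seq_len(width))] <- 0.9
  } else {
    theta <- init_theta
  }
  lambda <- 0.5
  ll_old <- -Inf; converged <- FALSE
  lbg <- matrix(log(bg), 4, width)
  llr <- NULL; z <- NULL; p_site <- NULL
  for (iter in seq_len(max_iter)) {
    lp_vec <- as.vector(log(theta) - lbg)
    llr <- as.vector(crossprod(M, lp_vec))
    a <- (lambda / m_of) * exp(pmin(llr, 700))
    denom_i <- (1 - lambda) + as.vector(S %*% a)
    z <- a / denom_i[seq_of]
    p_site <- 1 - (1 - lambda) / denom_i
    ll <- sum(u * log(denom_i))
    counts <- matrix(as.vector(M %*% (z * u_of)), nrow = 4) + 0.25
    rownames(counts) <- BASES
    theta <- sweep(counts, 2, colSums(counts), "/")
    lambda <- min(max(sum(u * p_site) / sum(u), 1e-4), 1 - 1e-4)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  # best site per sequence
  best <- tibble::tibble(seq = seq_of, llr = llr, z = z)
  best <- dplyr::slice_max(dplyr::group_by(best, .data$seq), .data$llr,
                           n = 1, with_ties = FALSE)
  list(theta = theta, lambda = lambda, score = ll_old, converged = converged,
       p_site = p_site, best = dplyr::ungroup(best))
}

# Best-of-n_starts ZOOPS EM fit for one width. Deterministic given the
# current RNG state.
# Best-of-n_starts ZOOPS fit. `refine` additionally polishes the phase of
# the winning fit: EM can lock onto a site alignment shifted by a column or
# two, so shifted copies of the converged PWM (vacated columns filled with
# background) are used as extra starts and the best likelihood kept. The
# unrefined score is retained alongside so significance calibration can
# compare like with like against decoy fits run without refinement.
zoops_em_fit <- function(sequences, weights, width, bg,
                         n_starts = 3, max_iter = 40, refine = FALSE) {
  enc <- lapply(sequences, encode_seq)
  wm <- window_matrix(enc, width)
  if (is.null(wm)) return(NULL)
  n_win <- nrow(wm$W)
  design <- em_design(wm, width)
  seeds <- sample.int(n_win, min(n_starts, n_win))
  fits <- lapply(seeds, function(s) {
    zoops_em_run(wm, weights, bg, width, s, design, max_iter = max_iter)
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "score"))]]
  best$base_score <- best$score
  if (refine) {
    for (shift in c(-2L, -1L, 1L, 2L)) {
      init <- matrix(bg, nrow = 4, ncol = width, dimnames = list(BASES, NULL))
      src <- seq_len(width) - shift
      ok <- src >= 1L & src <= width
      init[, ok] <- best$theta[, src[ok]]
      cand <- zoops_em_run(wm, weights, bg, width, 1L, design,
                           max_iter = max_iter, init_theta = init)
      if (cand$score > best$score) {
        cand$base_score <- best$base_score
        best <- cand
      }
    }
  }
  best
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide counts, by
#' sampling a random Eulerian walk on the dinucleotide transition multigraph
#' (rejection-sampled; falls back to shuffling the interior letters in the
#' rare event no walk is found).
#'
#' @param sequence Character scalar over ACGT.
#' @param max_tries Rejection-sampling attempts.
#' @return A shuffled sequence with identical dinucleotide composition.
#' @export
dinuc_shuffle <- function(sequence, max_tries = 100) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 3L) return(sequence)
  for (try in seq_len(max_tries)) {
    succ <- split(s[-1], s[-n])           # successor multisets per vertex
    succ <- lapply(succ, function(x) x[sample.int(length(x))])
    used <- lapply(succ, function(x) 0L)
    out <- character(n)
    out[1] <- s[1]
    ok <- TRUE
    v <- s[1]
    for (i in 2:n) {
      if (is.null(succ[[v]])) { ok <- FALSE; break }
      k <- used[[v]] + 1L
      if (k > length(succ[[v]])) { ok <- FALSE; break }
      used[[v]] <- k
      v <- succ[[v]][k]
      out[i] <- v
    }
    if (ok && all(mapply(function(u, sc) u == length(sc), used, succ[names(used)]))) {
      return(paste(out, collapse = ""))
    }
  }
  mid <- s[2:(n - 1L)]
  paste(c(s[1], mid[sample.int(length(mid))], s[n]), collapse = "")
}

# Gumbel upper-tail probability of `x` under a method-of-moments fit to the
# decoy best-score sample.
gumbel_tail <- function(x, decoy_scores) {
  m <- mean(decoy_scores); sdev <- stats::sd(decoy_scores)
  if (!is.finite(sdev) || sdev < 1e-9) {
    return(if (x > m + 1e-9) 0 else 1)
  }
  beta <- sdev * sqrt(6) / pi
  mu <- m - 0.57721566490153286 * beta
  -expm1(-exp(-(x - mu) / beta))
}

#' Per-column information content of a PWM (bitscore)
#'
#' The logo letter height of a column: `2 + sum(p * log2(p))` bits for a
#' 4-letter alphabet.
#'
#' @param matrix 4 x width probability matrix (rows A, C, G, T).
#' @return Numeric vector of per-column bits.
#' @export
pwm_information <- function(matrix) {
  apply(matrix, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Discover the dominant target motif of one guide by ZOOPS EM
#'
#' Fits a zero-or-one-occurrence-per-sequence PWM mixture to the target set
#' at each candidate width and calibrates its log-likelihood-ratio score
#' against `n_decoys` dinucleotide-shuffled decoy target sets: the E-value is
#' the Gumbel upper-tail probability of the observed score under the decoy
#' score distribution, multiplied by the number of widths tested. The best
#' width's motif is returned when its E-value passes
#' `thresholds$motif_evalue_max`; otherwise `NULL`.
#'
#' @param target_set Tibble with `sequence` and optional `weight` columns (as
#'   from [assemble_target_set()]), or a character vector.
#' @param width_range Candidate motif widths.
#' @param seed Integer seed; the whole discovery is deterministic given it.
#' @param thresholds A [trf_thresholds()] record.
#' @param n_decoys Decoy sets per width.
#' @param n_starts EM restarts per fit.
#' @param max_iter EM iteration cap.
#' @param force Return the best motif even when not significant.
#' @return A `trf_pwm` object or `NULL`.
#' @export
discover_motif <- function(target_set, width_range = 6:12, seed = 1L,
                           thresholds = trf_thresholds(),
                           n_decoys = 20L, n_starts = 3L, max_iter = 40L,
                           force = FALSE) {
  if (is.character(target_set)) {
    target_set <- tibble::tibble(sequence = target_set, weight = 1)
  }
  if (!"weight" %in% names(target_set)) target_set$weight <- 1
  seqs <- target_set$sequence
  weights <- target_set$weight
  if (length(seqs) < thresholds$min_motif_targets) {
    rlang::abort("insufficient target sequences for motif discovery",
                 class = "trf_insufficient_targets")
  }
  width_range <- width_range[width_range <= max(nchar(seqs))]
  width_range <- width_range[width_range >= 4L]
  if (!length(width_range)) rlang::abort("no admissible motif width")
  letters_all <- unlist(lapply(seqs, encode_seq))
  bg <- tabulate(letters_all[!is.na(letters_all)], 4) + 1
  bg <- bg / sum(bg)
  n_w <- length(width_range)
  res <- withr::with_seed(as.integer(seed), {
    decoy_sets <- lapply(seq_len(n_decoys), function(d) {
      vapply(seqs, dinuc_shuffle, character(1), USE.NAMES = FALSE)
    })
    lapply(width_range, function(w) {
      fit <- zoops_em_fit(seqs, weights, w, bg, n_starts, max_iter,
                          refine = TRUE)
      if (is.null(fit)) return(NULL)
      decoy_scores <- vapply(decoy_sets, function(dec) {
        dfit <- zoops_em_fit(dec, weights, w, bg, n_starts, max_iter)
        if (is.null(dfit)) -Inf else dfit$score
      }, numeric(1))
      # calibrate on the pre-refinement score: decoys are fit with the same
      # start protocol, refinement only polishes the reported matrix
      pval <- gumbel_tail(fit$base_score,
                          decoy_scores[is.finite(decoy_scores)])
      list(fit = fit, width = w, p = pval, e = min(pval * n_w, 1e300))
    })
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(NULL)
  best <- res[[which.min(vapply(res, `[[`, numeric(1), "e"))]]
  if (!force && best$e >= thresholds$motif_evalue_max) return(NULL)
  fit <- best$fit
  sites <- fit$best[fit$best$z > 0.5, ]
  new_trf_pwm(
    matrix = fit$theta, width = best$width, e_value = best$e,
    score = fit$score, n_sites = nrow(sites),
    n_targets = length(seqs), read_support = sum(weights),
    lambda = fit$lambda, converged = fit$converged
  )
}

new_trf_pwm <- function(matrix, width, e_value, score, n_sites, n_targets,
                        read_support, lambda = NA_real_, converged = TRUE,
                        trf_name = NA_character_, orientation = NA_character_,
                        trf_interval = c(NA_integer_, NA_integer_),
                        matchback_pvalue = NA_real_) {
  structure(list(
    matrix = matrix, width = as.integer(width), e_value = e_value,
    score = score, n_sites = n_sites, n_targets = n_targets,
    read_support = read_support, lambda = lambda, converged = converged,
    trf_name = trf_name, orientation = orientation,
    trf_interval = trf_interval, matchback_pvalue = matchback_pvalue
  ), class = "trf_pwm")
}

#' @export
print.trf_pwm <- function(x, ...) {
  cons <- paste(BASES[apply(x$matrix, 2, which.max)], collapse = "")
  cat(sprintf("<trf_pwm> width %d, consensus %s, E-value %.3g, %d/%d sites\n",
              x$width, cons, x$e_value, x$n_sites, x$n_targets))
  if (!is.na(x$trf_interval[1])) {
    cat(sprintf("  matches %s at [%d,%d], match-back p = %.3g\n",
                x$trf_name, x$trf_interval[1], x$trf_interval[2],
                x$matchback_pvalue))
  }
  invisible(x)
}

#' Tidy a fitted motif into a long tibble
#'
#' @param x A `trf_pwm` object.
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `probability`, `bits`.
#' @method tidy trf_pwm
#' @export
tidy.trf_pwm <- function(x, ...) {
  info <- pwm_information(x$matrix)
  tibble::tibble(
    position = rep(seq_len(x$width), each = 4),
    base = rep(BASES, x$width),
    probability = as.vector(x$matrix),
    bits = rep(info, each = 4)
  )
}

#' One-row summary of a fitted motif
#'
#' @param x A `trf_pwm` object.
#' @param ... Unused.
#' @return One-row tibble of motif-level statistics.
#' @method glance trf_pwm
#' @export
glance.trf_pwm <- function(x, ...) {
  tibble::tibble(
    trf_name = x$trf_name, orientation = x$orientation, width = x$width,
    e_value = x$e_value, score = x$score, n_sites = x$n_sites,
    n_targets = x$n_targets, read_support = x$read_support,
    matchback_pvalue = x$matchback_pvalue,
    trf_start = x$trf_interval[1], trf_end = x$trf_interval[2],
    converged = x$converged
  )
}

#' Write a motif matrix in the minimal text interchange format
#'
#' Plain text: `#`-prefixed metadata lines (`key: value`), an `ALPHABET`
#' line, a `WIDTH` line, then width rows of four probabilities.
#'
#' @param motif A `trf_pwm` object.
#' @param path Output file.
#' @return Invisibly, `motif`.
#' @export
write_motif_matrix <- function(motif, path) {
  meta <- c(
    sprintf("# trf_name: %s", motif$trf_name),
    sprintf("# orientation: %s", motif$orientation),
    sprintf("# e_value: %.10g", motif$e_value),
    sprintf("# n_sites: %d", motif$n_sites),
    sprintf("# trf_interval: %s",
            paste(motif$trf_interval, collapse = "-")),
    sprintf("# matchback_pvalue: %.10g", motif$matchback_pvalue),
    sprintf("ALPHABET %s", paste(BASES, collapse = " ")),
    sprintf("WIDTH %d", motif$width)
  )
  rows <- apply(motif$matrix, 2, function(p) paste(sprintf("%.8f", p), collapse = "\t"))
  writeLines(c(meta, rows), path)
  invisible(motif)
}

#' Read a motif matrix written by [write_motif_matrix()]
#'
#' @param path Input file.
#' @return A `trf_pwm` object (metadata fields restored where present).
#' @export
read_motif_matrix <- function(path) {
  ln <- readLines(path)
  meta <- ln[startsWith(ln, "#")]
  get_meta <- function(key, default = NA) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  width <- as.integer(sub("^WIDTH ", "", grep("^WIDTH ", ln, value = TRUE)[1]))
  rows <- ln[!startsWith(ln, "#") & !grepl("^(ALPHABET|WIDTH)", ln)]
  rows <- rows[nzchar(rows)]
  m <- t(vapply(strsplit(rows, "\t"), as.numeric, numeric(4)))
  stopifnot(nrow(m) == width)
  iv <- suppressWarnings(as.integer(strsplit(get_meta("trf_interval", "NA-NA"), "-")[[1]]))
  new_trf_pwm(
    matrix = matrix(t(m), nrow = 4, dimnames = list(BASES, NULL)),
    width = width,
    e_value = suppressWarnings(as.numeric(get_meta("e_value"))),
    score = NA_real_,
    n_sites = suppressWarnings(as.integer(get_meta("n_sites"))),
    n_targets = NA_integer_, read_support = NA_real_,
    trf_name = get_meta("trf_name"),
    orientation = get_meta("orientation"),
    trf_interval = iv,
    matchback_pvalue = suppressWarnings(as.numeric(get_meta("matchback_pvalue")))
  )
}
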