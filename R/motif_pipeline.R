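#' Assemble the unique target set of one guide
#'
#' Drops polyT-flagged targets (runs of at least `polyt_min_run` Ts),
#' collapses duplicate target sequences while summing their read support into
#' a weight, and reports whether enough distinct targets remain for motif
#' discovery.
#'
#' @param pairs Pair records (or decompositions) of a single guide and
#'   orientation, with `target_seq` and optionally `read_support` columns.
#' @param thresholds A [trf_thresholds()] record.
#' @return List with `targets` (tibble `sequence`, `weight`), `n_removed_polyt`
#'   and `status` ("ok" or "insufficient_targets").
#' @export
assemble_target_set <- function(pairs, thresholds = trf_thresholds()) {
  if (!"read_support" %in% names(pairs)) pairs$read_support <- 1L
  if (nrow(pairs) == 0L) {
    return(list(targets = tibble::tibble(sequence = character(0), weight = numeric(0)),
                n_removed_polyt = 0L, status = "insufficient_targets"))
  }
  rep_tbl <- polyt_report(pairs$target_seq, thresholds = thresholds)
  keep <- !rep_tbl$has_polyt_run
  kept <- pairs[keep, ]
  targets <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(sequence = kept$target_seq,
                                   weight = kept$read_support),
                    .data$sequence),
    weight = sum(.data$weight), .groups = "drop")
  list(
    targets = targets,
    n_removed_polyt = sum(!keep),
    status = if (nrow(targets) >= thresholds$min_motif_targets) "ok"
             else "insufficient_targets"
  )
}

#' Pool forward and reverse target sets and rediscover the motif
#'
#' Some guides have too few distinct targets in a single orientation; the
#' pooled, polyT-filtered target set combines the weak evidence and discovery
#' is rerun on it.
#'
#' @param fwd_targets,rev_targets Target tibbles (`sequence`, `weight`) as
#'   from [assemble_target_set()]; either may be empty.
#' @inheritParams discover_motif
#' @return A `trf_pwm` with orientation "combined", or `NULL`.
#' @export
combine_orientations <- function(fwd_targets, rev_targets,
                                 thresholds = trf_thresholds(), seed = 1L,
                                 width_range = 6:12, ...) {
  pooled <- dplyr::bind_rows(fwd_targets, rev_targets)
  pooled <- dplyr::summarise(dplyr::group_by(pooled, .data$sequence),
                             weight = sum(.data$weight), .groups = "drop")
  if (nrow(pooled) < thresholds$min_motif_targets) {
    rlang::abort("pooled target set below the minimum site count",
                 class = "trf_insufficient_targets")
  }
  motif <- discover_motif(pooled, width_range = width_range, seed = seed,
                          thresholds = thresholds, ...)
  if (!is.null(motif)) motif$orientation <- "combined"
  motif
}

# mean per-column Pearson correlation of two aligned PWMs; exact equality of
# zero-variance columns counts as 1
pwm_column_correlation <- function(a, b) {
  vals <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      return(if (max(abs(x - y)) < 1e-9) 1 else 0)
    }
    stats::cor(x, y)
  }, numeric(1))
  mean(vals)
}

#' Compare the forward and reverse motifs of one guide
#'
#' Both motifs must have been matched back onto the same guide coordinate
#' system. The comparison class is `identical` (equal guide intervals and
#' mean per-column matrix correlation >= 0.95), `overlap_ge4` (guide
#' intervals share at least 4 nt), `minimal_overlap` (1–3 nt), `disjoint`, or
#' `one_missing`.
#'
#' @param fwd,rev `trf_pwm` objects (either may be `NULL`).
#' @param trf_name Guide name recorded on the output.
#' @return One-row tibble (`trf_name`, `class`, `overlap_nt`, `fwd_start`,
#'   `rev_start`).
#' @export
compare_motifs <- function(fwd, rev, trf_name = NA_character_) {
  row <- function(class, overlap, fs, rs) {
    tibble::tibble(trf_name = trf_name, class = class,
                   overlap_nt = as.integer(overlap),
                   fwd_start = as.integer(fs), rev_start = as.integer(rs))
  }
  if (is.null(fwd) || is.null(rev) ||
      is.na(fwd$trf_interval[1]) || is.na(rev$trf_interval[1])) {
    return(row("one_missing", 0L,
               if (!is.null(fwd)) fwd$trf_interval[1] else NA,
               if (!is.null(rev)) rev$trf_interval[1] else NA))
  }
  fi <- fwd$trf_interval; ri <- rev$trf_interval
  overlap <- max(0L, min(fi[2], ri[2]) - max(fi[1], ri[1]) + 1L)
  cls <- if (all(fi == ri) && fwd$width == rev$width &&
             pwm_column_correlation(fwd$matrix, rev$matrix) >= 0.95) {
    "identical"
  } else if (overlap >= 4L) {
    "overlap_ge4"
  } else if (overlap >= 1L) {
    "minimal_overlap"
  } else {
    "disjoint"
  }
  row(cls, overlap, fi[1], ri[1])
}

#' Exact two-sided binomial test at even odds
#'
#' Shared significance machinery for the upstream–downstream motif test and
#' the conversion-site side-bias test: the exact two-sided binomial test of
#' `k` successes in `n` trials at success probability 0.5 (by symmetry equal
#' to doubling the smaller tail).
#'
#' @param k,n Successes and trials.
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' binomial_side_test(60, 85)  # 1.87e-4
binomial_side_test <- function(k, n) {
  if (n < 1L) rlang::abort("no untied observations", class = "trf_empty_input")
  stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
}

#' Upstream–downstream test on paired motif starts
#'
#' For guides with both a forward and a reverse motif at distinct guide
#' starts, counts how often the forward motif starts upstream (5') of the
#' reverse motif and tests the split against even odds with the exact
#' two-sided binomial test; ties are excluded.
#'
#' @param comparisons Tibble from [compare_motifs()] rows (needs `fwd_start`,
#'   `rev_start`).
#' @return List with `n_fwd_upstream`, `n_rev_upstream`, `p_value`.
#' @export
upstream_downstream_test <- function(comparisons) {
  ok <- !is.na(comparisons$fwd_start) & !is.na(comparisons$rev_start) &
    comparisons$fwd_start != comparisons$rev_start
  d <- comparisons[ok, ]
  n <- nrow(d)
  if (n == 0L) rlang::abort("no comparisons with distinct starts",
                            class = "trf_empty_input")
  k <- sum(d$fwd_start < d$rev_start)
  list(n_fwd_upstream = k, n_rev_upstream = n - k,
       p_value = binomial_side_test(k, n))
}

#' Rank motifs by multiple quality parameters
#'
#' Flags, for each parameter (number of unique targets, total read support,
#' E-value, match-back p-value), whether a motif sits in the top third of the
#' cohort; ties share the better rank, so equal values are flagged together.
#' Motifs in the top tercile of every parameter are marked high-confidence.
#'
#' @param motifs A list of matched `trf_pwm` objects or a tibble with columns
#'   `trf_name`, `n_targets`, `read_support`, `e_value`, `matchback_pvalue`.
#' @return The cohort tibble with `top_*` flags, `high_confidence`, sorted by
#'   the number of top-tercile parameters.
#' @export
rank_motifs <- function(motifs) {
  tbl <- if (is.data.frame(motifs)) {
    tibble::as_tibble(motifs)
  } else {
    purrr::map_dfr(motifs, glance.trf_pwm)
  }
  if (nrow(tbl) < 3L) rlang::abort("ranking needs a cohort of at least 3 motifs")
  n <- nrow(tbl)
  cut <- ceiling(n / 3)
  top <- function(x, bigger_better) {
    r <- if (bigger_better) dplyr::min_rank(dplyr::desc(x)) else dplyr::min_rank(x)
    r <= cut
  }
  tbl$top_n_targets <- top(tbl$n_targets, TRUE)
  tbl$top_read_support <- top(tbl$read_support, TRUE)
  tbl$top_e_value <- top(tbl$e_value, FALSE)
  tbl$top_matchback <- top(tbl$matchback_pvalue, FALSE)
  tbl$n_top <- tbl$top_n_targets + tbl$top_read_support +
    tbl$top_e_value + tbl$top_matchback
  tbl$high_confidence <- tbl$n_top == 4L
  dplyr::arrange(tbl, dplyr::desc(.data$n_top), .data$e_value)
}
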