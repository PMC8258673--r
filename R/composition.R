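DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))

#' Overlapping dinucleotide frequency vectors
#'
#' Counts all overlapping dinucleotides of each sequence and normalises by
#' the number of windows (length − 1). Ambiguity characters contribute to no
#' count; windows containing them are excluded from the denominator.
#' Sequences shorter than 2 nt yield an all-zero vector and a warning flag.
#'
#' @param sequences Character vector of sequences.
#' @param sequence_id Optional ids (default `seq_along`).
#' @return Tibble with `sequence_id`, one column per dinucleotide AA..TT, and
#'   a logical `too_short` flag.
#' @export
#' @examples
#' dinucleotide_vectors("ACGT")[, c("AC", "CG", "GT")]
dinucleotide_vectors <- function(sequences, sequence_id = NULL) {
  if (is.null(sequence_id)) sequence_id <- as.character(seq_along(sequences))
  mat <- matrix(0, nrow = length(sequences), ncol = 16,
                dimnames = list(NULL, DINUCS))
  too_short <- nchar(sequences) < 2L
  for (i in seq_along(sequences)) {
    if (too_short[i]) next
    s <- strsplit(sequences[i], "")[[1]]
    di <- paste0(s[-length(s)], s[-1])
    di <- di[di %in% DINUCS]
    if (length(di)) {
      tab <- table(factor(di, levels = DINUCS))
      mat[i, ] <- as.numeric(tab) / sum(tab)
    } else {
      too_short[i] <- TRUE
    }
  }
  if (any(too_short)) {
    rlang::warn("sequences with no countable dinucleotide return all-zero vectors")
  }
  dplyr::bind_cols(tibble::tibble(sequence_id = sequence_id),
                   tibble::as_tibble(mat),
                   tibble::tibble(too_short = too_short))
}

#' Principal-component projection of composition vectors
#'
#' Column-centred PCA (no scaling) of the 16 dinucleotide frequencies, with a
#' deterministic sign convention: within each component, the loading of
#' largest magnitude is made positive. Zero-variance columns are retained
#' with zero loadings.
#'
#' @param vectors Output of [dinucleotide_vectors()] (or any tibble whose
#'   numeric columns are the feature matrix).
#' @param n_components Number of components to return.
#' @return List of class `trf_pca` with `scores` (tibble, `sequence_id` +
#'   `PC1..`), `loadings` (matrix), and `explained_variance` (fractions, all
#'   components).
#' @export
pca_project <- function(vectors, n_components = 2L) {
  feats <- vectors[, intersect(DINUCS, names(vectors)), drop = FALSE]
  if (ncol(feats) == 0L) {
    feats <- vectors[, vapply(vectors, is.numeric, logical(1)), drop = FALSE]
  }
  X <- as.matrix(feats)
  if (nrow(X) < 3L) rlang::abort("PCA needs at least 3 vectors")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each PC made positive
  for (j in seq_len(ncol(fit$rotation))) {
    k <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[k, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2
  ev <- if (sum(ev) > 0) ev / sum(ev) else ev
  n_components <- min(n_components, ncol(fit$x))
  scores <- tibble::as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  if ("sequence_id" %in% names(vectors)) {
    scores <- dplyr::bind_cols(
      tibble::tibble(sequence_id = vectors$sequence_id), scores)
  }
  structure(list(scores = scores, loadings = fit$rotation,
                 explained_variance = ev, center = fit$center),
            class = "trf_pca")
}

#' @export
print.trf_pca <- function(x, ...) {
  cat(sprintf("<trf_pca> %d points; explained variance: %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance, 3)),
                    collapse = ", ")))
  invisible(x)
}

longest_t_run <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  if (!length(s)) return(list(len = 0L, start = NA_integer_, end = NA_integer_,
                              runs = cbind(start = integer(0), end = integer(0))))
  r <- rle(s == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr <- which(r$values)
  runs <- cbind(start = starts[tr], end = ends[tr])
  if (!nrow(runs)) return(list(len = 0L, start = NA_integer_, end = NA_integer_,
                               runs = runs))
  best <- which.max(runs[, 2] - runs[, 1])
  list(len = as.integer(max(runs[, 2] - runs[, 1] + 1L)),
       start = runs[best, 1], end = runs[best, 2], runs = runs)
}

#' polyT artifact report for target sequences
#'
#' Reports the longest run of consecutive Ts, whether it reaches
#' `polyt_min_run`, whether a qualifying run intersects the last
#' `polyt_tail_window` nucleotides, and the overall T fraction. Ambiguity
#' characters break runs.
#'
#' @param sequences Character vector of target sequences.
#' @param sequence_id Optional ids.
#' @param thresholds A [trf_thresholds()] record.
#' @return Tibble with `sequence_id`, `longest_t_run`, `has_polyt_run`,
#'   `long_run_in_tail`, `fraction_t`.
#' @export
polyt_report <- function(sequences, sequence_id = NULL,
                         thresholds = trf_thresholds()) {
  if (is.null(sequence_id)) sequence_id <- as.character(seq_along(sequences))
  k <- thresholds$polyt_min_run
  w <- thresholds$polyt_tail_window
  purrr::map2_dfr(sequences, sequence_id, function(sq, id) {
    n <- nchar(sq)
    info <- longest_t_run(sq)
    runs <- info$runs
    qual <- runs[runs[, 2] - runs[, 1] + 1L >= k, , drop = FALSE]
    tail_lo <- max(1L, n - w + 1L)
    in_tail <- nrow(qual) > 0 && any(qual[, 2] >= tail_lo)
    tibble::tibble(
      sequence_id = id,
      longest_t_run = info$len,
      has_polyt_run = info$len >= k,
      long_run_in_tail = in_tail,
      fraction_t = if (n > 0) stringr::str_count(sq, stringr::fixed("T")) / n else 0
    )
  })
}

#' Partition guide–target pairs by the polyT artifact flag
#'
#' Splits pairs into a clean set and a polyT set (target carries a T-run of
#' at least `polyt_min_run`) and reports the mean target T fraction of each
#' set. The partition is exact: the two sets are disjoint and jointly cover
#' the input.
#'
#' @param pairs Tibble with a `target_seq` column (e.g. `tally_pairs()$pairs`
#'   or decompositions).
#' @param thresholds A [trf_thresholds()] record.
#' @return List with `clean`, `polyt` (tibbles, input columns plus the polyT
#'   report) and `contrast` (one row per set with mean `fraction_t`).
#' @export
partition_by_polyt <- function(pairs, thresholds = trf_thresholds()) {
  rep_tbl <- polyt_report(pairs$target_seq, sequence_id = NULL, thresholds)
  rep_tbl$sequence_id <- NULL
  aug <- dplyr::bind_cols(pairs, rep_tbl)
  polyt <- aug[aug$has_polyt_run, ]
  clean <- aug[!aug$has_polyt_run, ]
  contrast <- tibble::tibble(
    set = c("clean", "polyt"),
    n = c(nrow(clean), nrow(polyt)),
    mean_fraction_t = c(mean(clean$fraction_t), mean(polyt$fraction_t))
  )
  list(clean = clean, polyt = polyt, contrast = contrast)
}
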