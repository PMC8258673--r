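#' Classify a tRF interval into one of the six coordinate-based types
#'
#' Fragments are typed by where they sit relative to the gene ends and the
#' anticodon loop, in this precedence (L = gene-body length, loop =
#' \[ls, le\]):
#'
#' * `3t` — ends at least 3 nt into the genomic 3' trailer (end >= L + 3 in
#'   body+trailer space); fragments starting after the gene end (often called
#'   tRF-1) fall in here too;
#' * `5p` — starts in the first 5 nt and ends before the anticodon loop;
#' * `5i` — starts in the first 5 nt and ends inside the anticodon loop
#'   (the "tRNA half" / 5' tiRNA class);
#' * `3p` — ends in the last 5 nt of the CCA-extended gene (end >= L - 1)
#'   and starts after the loop;
#' * `3i` — ends in the last 5 nt of the CCA-extended gene and starts inside
#'   the loop;
#' * `i`  — anything else (internal fragments).
#'
#' The precedence makes the classification total and deterministic even for
#' intervals that would satisfy several anchored rules.
#'
#' @param start,end 1-based closed interval, in the coordinate space given by
#'   `space` ("body", "cca" = body plus appended CCA, "trailer" = body plus
#'   genomic 3' flank). When `space` is `NULL` it is inferred: ends within
#'   the body are "body", ends at most 3 past the body are "cca", longer
#'   overhangs are "trailer".
#' @param model One gene model row.
#' @param space Coordinate space of `end` (see above), or `NULL` to infer.
#' @return One of "5p", "5i", "3p", "3i", "3t", "i".
#' @export
#' @examples
#' g <- gene_models("GluCTC-002", "N", strrep("ACGT", 18), 31, 39)
#' classify_trf(1, 33, g[1, ])  # "5i"
classify_trf <- function(start, end, model, space = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  L <- nchar(model$sequence[[1]])
  ls <- model$loop_start[[1]]; le <- model$loop_end[[1]]
  if (is.null(space)) {
    space <- if (end <= L) "body" else if (end <= L + 3L) "cca" else "trailer"
  }
  space <- match.arg(space, c("body", "cca", "trailer"))
  max_end <- switch(space, body = L, cca = L + 3L,
                    trailer = L + nchar(model$trailer[[1]]))
  if (start < 1L || end < start || end > max_end) {
    rlang::abort(sprintf("interval [%d,%d] outside %s space of %s (max %d)",
                         start, end, space, model$gene_id[[1]], max_end),
                 class = "trf_bad_interval")
  }
  if (space == "trailer" && end >= L + 3L) return("3t")
  if (start <= 5L && end < ls) return("5p")
  if (start <= 5L && end >= ls && end <= le) return("5i")
  if (end >= L - 1L && start > le) return("3p")
  if (end >= L - 1L && start >= ls && start <= le) return("3i")
  "i"
}

#' Canonical tRF name
#'
#' Builds the canonical `host_gene-origin-type-start-end` identifier, e.g.
#' `"GluCTC-002-N-5i-1-33"`. Vectorised; `parse_trf_name()` is its inverse.
#'
#' @param gene_id,origin,type,start,end Record fields (recycled).
#' @return Character vector of names.
#' @export
trf_name <- function(gene_id, origin, type, start, end) {
  paste(gene_id, origin, type, start, end, sep = "-")
}

#' Parse a canonical tRF name back into its fields
#'
#' @param name Character vector of canonical names produced by [trf_name()].
#' @return A tibble with columns `gene_id`, `origin`, `type`, `start`, `end`.
#' @export
parse_trf_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)
  purrr::map_dfr(parts, function(p) {
    n <- length(p)
    if (n < 5L) rlang::abort("not a canonical tRF name", class = "trf_bad_name")
    origin <- p[n - 3L]
    type <- p[n - 2L]
    if (!origin %in% c("N", "M", "NM") ||
        !type %in% c("5p", "5i", "3p", "3i", "3t", "i")) {
      rlang::abort("not a canonical tRF name", class = "trf_bad_name")
    }
    tibble::tibble(
      gene_id = paste(p[seq_len(n - 4L)], collapse = "-"),
      origin = origin, type = type,
      start = as.integer(p[n - 1L]), end = as.integer(p[n])
    )
  })
}

#' Length distribution of classified tRFs
#'
#' @param records Tibble with at least `trf_type` and either `length` or
#'   `trf_start`/`trf_end` columns; an optional `orientation` column is kept
#'   as a grouping variable.
#' @param weight Optional column name holding read counts (default: each row
#'   counts once).
#' @return Long tibble `(orientation?, type, length, count)`.
#' @export
length_distribution <- function(records, weight = NULL) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(type = character(0), length = integer(0),
                          count = integer(0)))
  }
  records <- dplyr::mutate(
    records,
    length = if ("length" %in% names(records)) .data$length
             else .data$trf_end - .data$trf_start + 1L
  )
  grp <- intersect(c("orientation"), names(records))
  w <- if (is.null(weight)) rep(1L, nrow(records)) else records[[weight]]
  records$..w <- w
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(c(grp, "trf_type", "length")))),
    count = sum(.data$..w), .groups = "drop")
  dplyr::rename(out, type = "trf_type")
}

# Isodecoder family key: the amino-acid + anticodon label preceding the gene
# copy number, e.g. "CysGCA" from "CysGCA-001-N-3p-58-75".
isodecoder_key <- function(trf_names) {
  vapply(strsplit(trf_names, "-", fixed = TRUE), `[[`, character(1), 1L)
}

#' Compare tRF abundance between forward and reverse chimeras
#'
#' Counts are converted to relative frequencies within each orientation
#' (over the union of items) and compared by Pearson correlation; per-item
#' fold changes (forward / reverse frequency) are reported. For items absent
#' on one side, a +0.5 pseudocount is applied to both sides of that item so
#' the fold change stays finite; items present on both sides use the exact
#' ratio.
#'
#' @param forward_counts,reverse_counts Tibbles with columns `name` and
#'   `count` (or named numeric vectors).
#' @param level "isoform" compares full tRF names; "isodecoder" pools counts
#'   by the parent anticodon family (leading name token).
#' @return A list of class `trf_orientation_comparison` with `$table`
#'   (`item`, `freq_fwd`, `freq_rev`, `fold_change`) and `$pearson_r`.
#' @export
compare_orientations <- function(forward_counts, reverse_counts,
                                 level = c("isoform", "isodecoder")) {
  level <- match.arg(level)
  as_tbl <- function(x) {
    if (is.data.frame(x)) tibble::tibble(name = x$name, count = x$count)
    else tibble::tibble(name = names(x), count = as.numeric(x))
  }
  f <- as_tbl(forward_counts); r <- as_tbl(reverse_counts)
  if (nrow(f) + nrow(r) == 0L) {
    rlang::abort("both orientations empty", class = "trf_empty_input")
  }
  if (level == "isodecoder") {
    f$name <- isodecoder_key(f$name); r$name <- isodecoder_key(r$name)
  }
  f <- dplyr::summarise(dplyr::group_by(f, .data$name),
                        count = sum(.data$count), .groups = "drop")
  r <- dplyr::summarise(dplyr::group_by(r, .data$name),
                        count = sum(.data$count), .groups = "drop")
  items <- sort(union(f$name, r$name))
  cf <- stats::setNames(rep(0, length(items)), items)
  cr <- cf
  cf[f$name] <- f$count; cr[r$name] <- r$count
  freq_f <- if (sum(cf) > 0) cf / sum(cf) else cf
  freq_r <- if (sum(cr) > 0) cr / sum(cr) else cr
  zero <- cf == 0 | cr == 0
  af <- ifelse(zero, cf + 0.5, cf); ar <- ifelse(zero, cr + 0.5, cr)
  fc <- (af / sum(cf + 0.5 * zero)) / (ar / sum(cr + 0.5 * zero))
  pearson <- if (length(items) >= 2L &&
                 stats::sd(freq_f) > 0 && stats::sd(freq_r) > 0) {
    stats::cor(freq_f, freq_r)
  } else NA_real_
  structure(list(
    table = tibble::tibble(item = items, freq_fwd = unname(freq_f),
                           freq_rev = unname(freq_r), fold_change = unname(fc)),
    pearson_r = pearson, level = level
  ), class = "trf_orientation_comparison")
}

#' @export
print.trf_orientation_comparison <- function(x, ...) {
  cat(sprintf("<trf_orientation_comparison> level = %s, items = %d, Pearson R = %s\n",
              x$level, nrow(x$table), format(x$pearson_r, digits = 4)))
  print(x$table, n = 10)
  invisible(x)
}
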