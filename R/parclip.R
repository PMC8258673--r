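align_one_parclip <- function(read_chars, gene_chars_list, gene_ids) {
  n <- length(read_chars)
  best_perfect <- NULL; best_onemm <- NULL
  for (gi in seq_along(gene_chars_list)) {
    g <- gene_chars_list[[gi]]
    Lg <- length(g)
    if (n > Lg) next
    for (off in seq_len(Lg - n + 1L)) {
      ref <- g[off:(off + n - 1L)]
      mm <- which(ref != read_chars)
      if (length(mm) == 0L) {
        cand <- list(gene = gene_ids[gi], start = off, conv = NA_integer_)
        if (is.null(best_perfect)) best_perfect <- cand
      } else if (length(mm) == 1L && is.null(best_perfect) &&
                 ref[mm] == "T" && read_chars[mm] == "C") {
        cand <- list(gene = gene_ids[gi], start = off,
                     conv = off + mm - 1L)
        if (is.null(best_onemm)) best_onemm <- cand
      }
    }
    if (!is.null(best_perfect)) break  # genes scanned in id order
  }
  if (!is.null(best_perfect)) c(best_perfect, mismatches = 0L)
  else if (!is.null(best_onemm)) c(best_onemm, mismatches = 1L)
  else NULL
}

#' Align PAR-CLIP reads to the tRNA reference
#'
#' End-to-end exact alignment against each gene's CCA-extended sequence,
#' preferring perfect matches; otherwise exactly one mismatch is tolerated
#' and only when the reference base is T and the read base is C (the
#' crosslinking-induced conversion). Reads shorter than `min_parclip_read`
#' are excluded. Ambiguous placements are counted once against the
#' lexicographically smallest gene at the 5'-most offset.
#'
#' @param reads Tibble with `read_id`, `sequence`, and optionally `sample`.
#' @param models A `trf_gene_models` tibble.
#' @param thresholds A [trf_thresholds()] record.
#' @return List with `alignments` (tibble `read_id`, `sample`, `gene_id`,
#'   `gene_start`, `gene_end`, `mismatches`, `conversion_pos`) and counts of
#'   `n_too_short` and `n_unaligned` reads.
#' @export
align_parclip_reads <- function(reads, models, thresholds = trf_thresholds()) {
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  too_short <- nchar(reads$sequence) < thresholds$min_parclip_read
  kept <- reads[!too_short, ]
  ord <- order(models$gene_id)
  # each gene contributes its CCA-extended mature sequence and, where a
  # trailer is annotated, its trailer-extended sequence (same body coords)
  gene_ids <- character(0); gene_chars <- list()
  for (i in ord) {
    spaces <- c(if (models$cca_added[i]) "cca" else "body",
                if (nchar(models$trailer[i]) > 0L) "trailer")
    for (sp in spaces) {
      gene_ids <- c(gene_ids, models$gene_id[i])
      gene_chars[[length(gene_chars) + 1L]] <-
        strsplit(extended_sequence(models$sequence[i], models$trailer[i], sp),
                 "")[[1]]
    }
  }
  uniq <- unique(kept$sequence)
  hits <- lapply(uniq, function(sq) {
    align_one_parclip(strsplit(sq, "")[[1]], gene_chars, gene_ids)
  })
  aligned <- !vapply(hits, is.null, logical(1))
  u_start <- u_conv <- u_mm <- rep(NA_integer_, length(uniq))
  u_gene <- rep(NA_character_, length(uniq))
  u_gene[aligned] <- vapply(hits[aligned], function(h) h$gene, character(1))
  u_start[aligned] <- vapply(hits[aligned], function(h) as.integer(h$start),
                             integer(1))
  u_conv[aligned] <- vapply(hits[aligned], function(h) as.integer(h$conv),
                            integer(1))
  u_mm[aligned] <- vapply(hits[aligned], function(h) as.integer(h$mismatches),
                          integer(1))
  j <- match(kept$sequence, uniq)
  ok <- aligned[j]
  rows <- tibble::tibble(
    read_id = kept$read_id[ok], sample = kept$sample[ok],
    gene_id = u_gene[j][ok], gene_start = u_start[j][ok],
    gene_end = u_start[j][ok] + nchar(kept$sequence[ok]) - 1L,
    mismatches = u_mm[j][ok], conversion_pos = u_conv[j][ok])
  list(alignments = rows,
       n_too_short = sum(too_short),
       n_unaligned = nrow(kept) - nrow(rows))
}

#' RPM-normalised T->C conversion profile
#'
#' Each conversion event contributes `1e6 / sample_total` reads-per-million
#' at its gene position; samples are normalised separately and then summed.
#' The top conversion site per gene is the position of maximal combined
#' frequency, ties broken 5'-most (and flagged).
#'
#' @param alignments Alignment tibble from [align_parclip_reads()].
#' @param sample_totals Named numeric vector: total aligned reads per sample
#'   (the RPM denominator).
#' @return List of class `trf_conversion_profile` with `profile` (tibble
#'   `gene_id`, `position`, `rpm`, `depth`) and `top_sites` (tibble
#'   `gene_id`, `top_site`, `rpm`, `tied`; `top_site` is `NA` for genes with
#'   no conversions).
#' @export
conversion_profile <- function(alignments, sample_totals) {
  if (any(sample_totals <= 0) || anyNA(sample_totals)) {
    rlang::abort("sample totals must be positive", class = "trf_bad_threshold")
  }
  missing <- setdiff(unique(alignments$sample), names(sample_totals))
  if (length(missing)) {
    rlang::abort(paste("no total for sample:", paste(missing, collapse = ", ")))
  }
  conv <- alignments[!is.na(alignments$conversion_pos), ]
  conv$rpm <- 1e6 / sample_totals[conv$sample]
  profile <- dplyr::summarise(
    dplyr::group_by(conv, gene_id = .data$gene_id, position = .data$conversion_pos),
    rpm = sum(.data$rpm), .groups = "drop")
  # raw read depth per covered position, all samples pooled
  lens <- alignments$gene_end - alignments$gene_start + 1L
  depth <- tibble::tibble(
    gene_id = rep(alignments$gene_id, lens),
    position = sequence(lens) + rep(alignments$gene_start, lens) - 1L)
  depth <- dplyr::count(depth, .data$gene_id, .data$position, name = "depth")
  profile <- dplyr::left_join(profile, depth, by = c("gene_id", "position"))
  profile <- dplyr::arrange(profile, .data$gene_id, .data$position)
  tops <- purrr::map_dfr(unique(alignments$gene_id), function(g) {
    p <- profile[profile$gene_id == g, ]
    if (nrow(p) == 0L) {
      return(tibble::tibble(gene_id = g, top_site = NA_integer_,
                            rpm = 0, tied = FALSE))
    }
    mx <- max(p$rpm)
    at <- p$position[p$rpm >= mx - 1e-12]
    tibble::tibble(gene_id = g, top_site = min(at), rpm = mx,
                   tied = length(at) > 1L)
  })
  structure(list(profile = profile, top_sites = tops),
            class = "trf_conversion_profile")
}

#' @export
print.trf_conversion_profile <- function(x, ...) {
  cat(sprintf("<trf_conversion_profile> %d genes, %d conversion positions\n",
              nrow(x$top_sites), nrow(x$profile)))
  print(x$top_sites, n = 6)
  invisible(x)
}

#' Map conversion sites across species through fully matching tRFs
#'
#' Fragments from one species that match a reference gene of the other
#' species exactly and over their full length have their conversion positions
#' translated through the match offset; anything with even one mismatch is
#' dropped (and counted).
#'
#' @param other_trfs Tibble with `trf_id`, `sequence`, `conversion_pos`
#'   (1-based position on the fragment).
#' @param reference_models Target-species `trf_gene_models`.
#' @return List with `mapped` (tibble `trf_id`, `gene_id`, `offset`,
#'   `ref_position`) and `n_dropped`.
#' @export
map_cross_species <- function(other_trfs, reference_models) {
  ord <- order(reference_models$gene_id)
  refs <- stats::setNames(
    ifelse(reference_models$cca_added[ord],
           paste0(reference_models$sequence[ord], "CCA"),
           reference_models$sequence[ord]),
    reference_models$gene_id[ord])
  mapped <- purrr::map_dfr(seq_len(nrow(other_trfs)), function(i) {
    hit <- stringr::str_locate(refs, stringr::fixed(other_trfs$sequence[i]))
    k <- which(!is.na(hit[, 1]))
    if (!length(k)) return(NULL)
    k <- k[1]  # refs sorted by gene_id: canonical choice
    off <- as.integer(hit[k, 1]) - 1L
    tibble::tibble(trf_id = other_trfs$trf_id[i],
                   gene_id = names(refs)[k],
                   offset = off,
                   ref_position = other_trfs$conversion_pos[i] + off)
  })
  list(mapped = mapped, n_dropped = nrow(other_trfs) -
         if (is.null(mapped)) 0L else nrow(mapped))
}

#' Cumulative motif bitscores around the top conversion site
#'
#' Aligns every motif-containing guide so its most frequent conversion site
#' sits at offset 0 and accumulates each motif column's information content
#' (logo height, bits) at its guide position minus the conversion site.
#' Guides without a top site are skipped and counted.
#'
#' @param motifs List of matched `trf_pwm` objects (guide intervals set by
#'   [match_back()]).
#' @param top_sites Tibble with `trf_name` and `top_site` (1-based position
#'   on the guide sequence).
#' @return List of class `trf_bitscore_histogram` with `histogram` (tibble
#'   `offset`, `cumulative_bits`, `n_trfs`), `per_trf` (tibble `trf_name`,
#'   `upstream_bits`, `downstream_bits`) and `n_skipped`.
#' @export
bitscore_histogram <- function(motifs, top_sites) {
  placements <- list(); skipped <- 0L
  for (m in motifs) {
    site <- top_sites$top_site[match(m$trf_name, top_sites$trf_name)]
    if (length(site) != 1L || is.na(site) || is.na(m$trf_interval[1])) {
      skipped <- skipped + 1L
      next
    }
    bits <- pwm_information(m$matrix)
    pos <- seq(m$trf_interval[1], m$trf_interval[2])
    placements[[length(placements) + 1L]] <-
      tibble::tibble(trf_name = m$trf_name, offset = pos - site, bits = bits)
  }
  pl <- dplyr::bind_rows(placements)
  if (nrow(pl) == 0L) {
    return(structure(list(
      histogram = tibble::tibble(offset = integer(0),
                                 cumulative_bits = numeric(0), n_trfs = integer(0)),
      per_trf = tibble::tibble(trf_name = character(0),
                               upstream_bits = numeric(0), downstream_bits = numeric(0)),
      n_skipped = skipped), class = "trf_bitscore_histogram"))
  }
  hist <- dplyr::summarise(dplyr::group_by(pl, .data$offset),
                           cumulative_bits = sum(.data$bits),
                           n_trfs = dplyr::n_distinct(.data$trf_name),
                           .groups = "drop")
  per_trf <- dplyr::summarise(dplyr::group_by(pl, .data$trf_name),
                              upstream_bits = sum(.data$bits[.data$offset < 0]),
                              downstream_bits = sum(.data$bits[.data$offset > 0]),
                              .groups = "drop")
  structure(list(histogram = dplyr::arrange(hist, .data$offset),
                 per_trf = per_trf, n_skipped = skipped),
            class = "trf_bitscore_histogram")
}

#' @export
print.trf_bitscore_histogram <- function(x, ...) {
  cat(sprintf("<trf_bitscore_histogram> %d guides, offsets %s..%s (%d skipped)\n",
              nrow(x$per_trf),
              if (nrow(x$histogram)) min(x$histogram$offset) else NA,
              if (nrow(x$histogram)) max(x$histogram$offset) else NA,
              x$n_skipped))
  invisible(x)
}

#' Side-bias test of motif mass around the conversion site
#'
#' Each guide votes for the side (5' vs 3' of its top conversion site)
#' carrying more motif bitscore mass; ties are excluded and the split is
#' tested against even odds with the exact two-sided binomial test shared
#' with [upstream_downstream_test()].
#'
#' @param x A `trf_bitscore_histogram` or its `per_trf` tibble.
#' @return List with `n_upstream`, `n_downstream`, `p_value`.
#' @export
side_bias_test <- function(x) {
  per_trf <- if (inherits(x, "trf_bitscore_histogram")) x$per_trf else x
  diff <- per_trf$upstream_bits - per_trf$downstream_bits
  untied <- abs(diff) > 1e-12
  n <- sum(untied)
  if (n == 0L) rlang::abort("no untied guides", class = "trf_empty_input")
  k <- sum(diff[untied] > 0)
  list(n_upstream = k, n_downstream = n - k,
       p_value = binomial_side_test(k, n))
}
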