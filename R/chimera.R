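#' Build an exact-substring index over tRNA gene extended sequences
#'
#' Guide arms are matched exactly (no mismatches) against each gene in its
#' mature coordinate spaces: the gene body with appended CCA (covering plain
#' body matches) and, where a trailer is annotated, the body plus genomic 3'
#' trailer.
#'
#' @param models A `trf_gene_models` tibble.
#' @return An index of class `trf_gene_index`.
#' @export
build_gene_index <- function(models) {
  stopifnot(nrow(models) > 0L)
  cca <- ifelse(models$cca_added,
                paste0(models$sequence, "CCA"), models$sequence)
  trail <- ifelse(nchar(models$trailer) > 0L,
                  paste0(models$sequence, models$trailer), NA_character_)
  structure(list(
    models = models,
    gene_id = models$gene_id,
    body_len = nchar(models$sequence),
    cca_seq = cca,
    trailer_seq = trail,
    search_seq = c(cca, trail[!is.na(trail)]),
    search_gene = c(seq_len(nrow(models)), which(!is.na(trail))),
    search_space = c(rep("cca", nrow(models)),
                     rep("trailer", sum(!is.na(trail))))
  ), class = "trf_gene_index")
}

# All gene placements of an exact arm sequence. CCA space is preferred over
# trailer space for the same gene; a match whose end stays inside the gene
# body is reported as body space.
arm_gene_matches <- function(arm, index) {
  hit <- stringr::str_locate(index$search_seq, stringr::fixed(arm))
  keep <- which(!is.na(hit[, 1]))
  if (!length(keep)) return(NULL)
  out <- tibble::tibble(
    gene_id = index$gene_id[index$search_gene[keep]],
    space = index$search_space[keep],
    gene_start = as.integer(hit[keep, 1]),
    gene_end = as.integer(hit[keep, 2]),
    body_len = index$body_len[index$search_gene[keep]]
  )
  out$space[out$gene_end <= out$body_len] <- "body"
  # one placement per gene: prefer body, then cca, then trailer
  pref <- c(body = 1L, cca = 2L, trailer = 3L)
  out <- dplyr::arrange(out, .data$gene_id, pref[.data$space])
  out <- out[!duplicated(out$gene_id), ]
  dplyr::arrange(out, .data$gene_id)
}

#' Find the anchored tRF arm of a chimeric read
#'
#' Forward chimeras carry the guide on the 5' end: the arm is the longest
#' read prefix exactly matching some gene's extended sequence. Reverse
#' chimeras carry the guide on the 3' end: the arm is the longest such read
#' suffix ("the longest tRNA-matching sequence ending at the last nucleotide
#' of the read"). Matches shorter than `min_trf_arm` are discarded.
#'
#' @param read_sequence Read sequence (character scalar).
#' @param gene_index A `trf_gene_index`.
#' @param orientation "forward" or "reverse".
#' @param thresholds A [trf_thresholds()] record.
#' @return `NULL` if no qualifying arm, else a list with `read_start`,
#'   `read_end`, `arm` (sequence) and `genes` (tibble of gene placements).
#' @export
find_trf_arm <- function(read_sequence, gene_index,
                         orientation = c("forward", "reverse"),
                         thresholds = trf_thresholds()) {
  orientation <- match.arg(orientation)
  n <- nchar(read_sequence)
  if (is.na(read_sequence) || n == 0L) {
    rlang::abort("empty read", class = "trf_empty_read")
  }
  kmin <- thresholds$min_trf_arm
  if (n < kmin) return(NULL)
  sub_at <- function(k) {
    if (orientation == "forward") substr(read_sequence, 1L, k)
    else substr(read_sequence, n - k + 1L, n)
  }
  matches_at <- function(k) {
    any(stringr::str_detect(gene_index$search_seq,
                            stringr::fixed(sub_at(k))))
  }
  if (!matches_at(kmin)) return(NULL)
  # matchability is monotone in arm length (any substring of a match also
  # matches), so binary search for the longest matching anchor
  lo <- kmin; hi <- n
  if (matches_at(hi)) {
    lo <- hi
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (matches_at(mid)) lo <- mid else hi <- mid
    }
  }
  k <- lo
  arm <- sub_at(k)
  list(
    read_start = if (orientation == "forward") 1L else n - k + 1L,
    read_end = if (orientation == "forward") k else n,
    arm = arm,
    genes = arm_gene_matches(arm, gene_index)
  )
}

# Construct the classified tRF record for the canonical (lexicographically
# smallest) gene among equally long placements.
arm_to_trf_record <- function(arm, index) {
  g <- arm$genes
  canon <- g[1, ]
  model <- index$models[index$models$gene_id == canon$gene_id, ]
  type <- classify_trf(canon$gene_start, canon$gene_end, model,
                       space = canon$space)
  tibble::tibble(
    trf_name = trf_name(canon$gene_id, model$origin, type,
                        canon$gene_start, canon$gene_end),
    gene_id = canon$gene_id,
    origin = model$origin,
    trf_type = type,
    trf_start = canon$gene_start,
    trf_end = canon$gene_end,
    trf_space = canon$space,
    trf_seq = arm$arm,
    ambiguity = list(g$gene_id)
  )
}

#' Annotate a target arm against the transcript reference
#'
#' The target segment is located by exact substring match; among several
#' matching transcripts the lexicographically smallest id is chosen (and all
#' ids are reported). For mRNA, the region label is assigned by majority
#' overlap with the annotated regions, ties broken by the precedence
#' 3UTR > CDS > 5UTR > intron.
#'
#' @param target_sequence Target arm sequence.
#' @param transcripts A `trf_transcript_models` tibble.
#' @return One-row tibble (`transcript_id`, `category`, `region`,
#'   `tx_start`, `tx_end`, `tx_hits`) or `NULL` when unannotated.
#' @export
annotate_target <- function(target_sequence, transcripts) {
  hits <- which(stringr::str_detect(transcripts$sequence,
                                    stringr::fixed(target_sequence)))
  if (!length(hits)) return(NULL)
  ids <- transcripts$transcript_id[hits]
  pick <- hits[order(ids)[1]]
  pos <- stringr::str_locate(transcripts$sequence[pick],
                             stringr::fixed(target_sequence))
  s <- as.integer(pos[1, 1]); e <- as.integer(pos[1, 2])
  region <- NA_character_
  if (transcripts$category[pick] == "mRNA") {
    r <- transcripts$regions[[pick]]
    if (nrow(r)) {
      ov <- pmin(r$end, e) - pmax(r$start, s) + 1L
      r <- r[ov > 0, ]; ov <- ov[ov > 0]
      if (length(ov)) {
        prec <- c("3UTR" = 1L, "CDS" = 2L, "5UTR" = 3L, "intron" = 4L)
        ord <- order(-ov, prec[r$region])
        region <- r$region[ord[1]]
      }
    }
  }
  tibble::tibble(
    transcript_id = transcripts$transcript_id[pick],
    category = transcripts$category[pick],
    region = region, tx_start = s, tx_end = e,
    tx_hits = list(sort(ids))
  )
}

#' Classify a read as a tRF–tRF chimera
#'
#' Reads with qualifying anchored guide arms on both ends, not overlapping on
#' the read, are tRF–tRF chimeras: `same_gene_disjoint` when both arms place
#' on one gene at non-overlapping gene intervals (stem-like intramolecular
#' pairs), `different_gene_pair` otherwise.
#'
#' @inheritParams find_trf_arm
#' @param read Read sequence.
#' @return "different_gene_pair", "same_gene_disjoint" or "not_trf_trf".
#' @export
detect_trf_trf <- function(read, gene_index, thresholds = trf_thresholds()) {
  fwd <- find_trf_arm(read, gene_index, "forward", thresholds)
  if (is.null(fwd) || is.null(fwd$genes)) return("not_trf_trf")
  rev <- find_trf_arm(read, gene_index, "reverse", thresholds)
  if (is.null(rev) || is.null(rev$genes)) return("not_trf_trf")
  n <- nchar(read)
  if (fwd$read_end >= rev$read_start) {
    # greedy arms may overrun each other by a few chance-matching bases;
    # trim one arm back so the two partition the read, if both stay long
    # enough to qualify
    trim_fwd <- rev$read_start - 1L
    trim_rev <- n - fwd$read_end
    if (trim_fwd >= thresholds$min_trf_arm) {
      arm <- substr(read, 1L, trim_fwd)
      fwd <- list(read_start = 1L, read_end = trim_fwd, arm = arm,
                  genes = arm_gene_matches(arm, gene_index))
    } else if (trim_rev >= thresholds$min_trf_arm) {
      arm <- substr(read, n - trim_rev + 1L, n)
      rev <- list(read_start = n - trim_rev + 1L, read_end = n, arm = arm,
                  genes = arm_gene_matches(arm, gene_index))
    } else {
      return("not_trf_trf")
    }
  }
  shared <- intersect(fwd$genes$gene_id, rev$genes$gene_id)
  for (g in shared) {
    a <- fwd$genes[fwd$genes$gene_id == g, ]
    b <- rev$genes[rev$genes$gene_id == g, ]
    if (a$gene_end < b$gene_start || b$gene_end < a$gene_start) {
      return("same_gene_disjoint")
    }
  }
  if (length(shared) == length(union(fwd$genes$gene_id, rev$genes$gene_id))) {
    return("not_trf_trf")
  }
  "different_gene_pair"
}

#' Decompose a chimeric read into guide and target arms
#'
#' The anchored guide arm is found with [find_trf_arm()]; the remainder of
#' the read is the target arm. Reads are rejected (with an enumerated
#' reason) when no arm is found (`no_trf_arm`), when the arm covers at least
#' `trna_fraction_max` of the read (`trna_dominated`), when the target arm is
#' shorter than `min_target_arm` (`target_too_short`), or when the target
#' matches no reference transcript (`target_unannotated`).
#'
#' @param read_id Read identifier.
#' @param read Read sequence.
#' @param gene_index A `trf_gene_index`.
#' @param transcripts A `trf_transcript_models` tibble.
#' @param orientation "forward" or "reverse".
#' @param thresholds A [trf_thresholds()] record.
#' @return One-row decomposition tibble, or a character rejection reason with
#'   class `trf_rejection`.
#' @export
split_read <- function(read_id, read, gene_index, transcripts,
                       orientation = c("forward", "reverse"),
                       thresholds = trf_thresholds()) {
  orientation <- match.arg(orientation)
  reject <- function(reason) structure(reason, class = "trf_rejection")
  arm <- find_trf_arm(read, gene_index, orientation, thresholds)
  if (is.null(arm)) return(reject("no_trf_arm"))
  n <- nchar(read)
  arm_len <- arm$read_end - arm$read_start + 1L
  if (arm_len / n >= thresholds$trna_fraction_max) {
    return(reject("trna_dominated"))
  }
  if (orientation == "forward") {
    t_start <- arm$read_end + 1L; t_end <- n
  } else {
    t_start <- 1L; t_end <- arm$read_start - 1L
  }
  target <- substr(read, t_start, t_end)
  if (nchar(target) < thresholds$min_target_arm) {
    return(reject("target_too_short"))
  }
  ann <- annotate_target(target, transcripts)
  if (is.null(ann)) return(reject("target_unannotated"))
  trf <- arm_to_trf_record(arm, gene_index)
  dplyr::bind_cols(
    tibble::tibble(read_id = read_id, orientation = orientation,
                   read_length = n),
    trf,
    tibble::tibble(target_seq = target,
                   target_read_start = t_start, target_read_end = t_end),
    ann
  )
}

#' Decompose a batch of chimeric reads
#'
#' Applies [detect_trf_trf()] first (tRF–tRF chimeras are excluded from the
#' tRF–target stream) and then [split_read()] to every read. When
#' `orientation = "both"`, forward decomposition is attempted first and
#' reverse is used as fallback; the recorded rejection reason is that of the
#' last attempt.
#'
#' @param reads Tibble with columns `read_id` and `sequence` (see
#'   [read_sequences()]).
#' @inheritParams split_read
#' @param orientation "forward", "reverse" or "both".
#' @return List with `decompositions` (tibble), `trf_trf` (tibble of
#'   read_id/classification), and `rejections` (tibble of read_id/reason).
#' @export
split_reads <- function(reads, gene_index, transcripts,
                        orientation = c("both", "forward", "reverse"),
                        thresholds = trf_thresholds()) {
  orientation <- match.arg(orientation)
  tries <- if (orientation == "both") c("forward", "reverse") else orientation
  decomps <- list(); rej <- list(); tt <- list()
  for (i in seq_len(nrow(reads))) {
    id <- reads$read_id[i]; sq <- reads$sequence[i]
    cls <- detect_trf_trf(sq, gene_index, thresholds)
    if (cls != "not_trf_trf") {
      tt[[length(tt) + 1L]] <- tibble::tibble(read_id = id, classification = cls)
      next
    }
    res <- NULL
    for (ori in tries) {
      res <- split_read(id, sq, gene_index, transcripts, ori, thresholds)
      if (!inherits(res, "trf_rejection")) break
    }
    if (inherits(res, "trf_rejection")) {
      rej[[length(rej) + 1L]] <- tibble::tibble(read_id = id,
                                                reason = unclass(res))
    } else {
      decomps[[length(decomps) + 1L]] <- res
    }
  }
  list(
    decompositions = dplyr::bind_rows(decomps),
    trf_trf = dplyr::bind_rows(tt),
    rejections = dplyr::bind_rows(rej)
  )
}

#' Tally guide–target pairs and summarise support
#'
#' Collapses decompositions to unique (tRF, target interval, orientation)
#' pairs with read support, and produces the summary table of read counts by
#' tRF type, target category and orientation, with the at-least-two-read
#' subtotal in a separate column.
#'
#' @param decompositions Decomposition tibble from [split_reads()].
#' @return List with `pairs` and `summary` tibbles.
#' @export
tally_pairs <- function(decompositions) {
  if (is.null(decompositions) || nrow(decompositions) == 0L) {
    return(list(
      pairs = tibble::tibble(trf_name = character(0), transcript_id = character(0),
                             tx_start = integer(0), tx_end = integer(0),
                             orientation = character(0), read_support = integer(0),
                             two_read_supported = logical(0)),
      summary = tibble::tibble(trf_type = character(0), category = character(0),
                               orientation = character(0), reads = integer(0),
                               reads_two_plus = integer(0))
    ))
  }
  pairs <- dplyr::summarise(
    dplyr::group_by(decompositions, .data$trf_name, .data$trf_type,
                    .data$transcript_id, .data$category,
                    .data$tx_start, .data$tx_end, .data$orientation),
    read_support = dplyr::n(),
    target_seq = .data$target_seq[1],
    .groups = "drop")
  pairs$two_read_supported <- pairs$read_support >= 2L
  summary <- dplyr::summarise(
    dplyr::group_by(pairs, .data$trf_type, .data$category, .data$orientation),
    reads = sum(.data$read_support),
    reads_two_plus = sum(.data$read_support[.data$two_read_supported]),
    .groups = "drop")
  list(pairs = pairs, summary = summary)
}

#' Read sequences from FASTA or FASTQ into a tibble
#'
#' Qualities are ignored; identifiers are truncated at the first whitespace.
#'
#' @param path Input file; format inferred from the extension unless given.
#' @param format "fasta", "fastq" or NULL to infer.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = normalise_sequence(as.character(x))
  )
}
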