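#' @importFrom rlang .data
NULL

normalise_sequence <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# "10-25,40-52" -> integer matrix with columns start,end; "" -> 0-row matrix
parse_intron_field <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- t(vapply(strsplit(parts, "-", fixed = TRUE), function(p) {
    if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p)))) {
      rlang::abort(paste0("malformed intron interval: ", paste(p, collapse = "-")),
                   class = "trf_bad_interval")
    }
    as.integer(p)
  }, integer(2)))
  colnames(m) <- c("start", "end")
  m
}

format_intron_field <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
}

validate_gene_models <- function(models) {
  stopifnot(is.data.frame(models))
  need <- c("gene_id", "origin", "sequence", "loop_start", "loop_end",
            "introns", "trailer", "cca_added")
  miss <- setdiff(need, names(models))
  if (length(miss)) {
    rlang::abort(paste("gene model table missing columns:",
                       paste(miss, collapse = ", ")))
  }
  dup <- models$gene_id[duplicated(models$gene_id)]
  if (length(dup)) {
    rlang::abort(paste("duplicate gene_id:", paste(unique(dup), collapse = ", ")),
                 class = "trf_duplicate_gene")
  }
  bad_origin <- setdiff(unique(models$origin), c("N", "M", "NM"))
  if (length(bad_origin)) {
    rlang::abort(paste("origin must be N, M or NM; got", paste(bad_origin, collapse = ", ")))
  }
  for (i in seq_len(nrow(models))) {
    gid <- models$gene_id[i]
    L <- nchar(models$sequence[i])
    if (grepl("[^ACGT]", models$sequence[i])) {
      rlang::abort(paste0(gid, ": gene sequence contains non-ACGT characters"),
                   class = "trf_bad_sequence")
    }
    ls <- models$loop_start[i]; le <- models$loop_end[i]
    if (is.na(ls) || is.na(le) || ls < 1L || le < ls || le > L) {
      rlang::abort(paste0(gid, ": anticodon loop [", ls, ",", le,
                          "] out of bounds for length ", L),
                   class = "trf_bad_interval")
    }
    introns <- models$introns[[i]]
    if (nrow(introns)) {
      if (any(introns[, 1] > introns[, 2]) || any(introns[, 1] < 1L) ||
          any(introns[, 2] > L)) {
        rlang::abort(paste0(gid, ": intron interval outside [1,", L, "]"),
                     class = "trf_bad_interval")
      }
      if (is.unsorted(as.vector(t(introns)), strictly = TRUE)) {
        rlang::abort(paste0(gid, ": introns must be sorted and disjoint"),
                     class = "trf_bad_interval")
      }
    }
    if (grepl("[^ACGT]", models$trailer[i])) {
      rlang::abort(paste0(gid, ": trailer contains non-ACGT characters"),
                   class = "trf_bad_sequence")
    }
  }
  models
}

#' Build a tRNA gene-model table
#'
#' Assembles and validates the table of tRNA gene models used throughout the
#' pipeline. Coordinates are 1-based, closed, on the gene body (introns
#' included). The mature 3' end may carry an appended CCA; alternatively a
#' fragment may run into the genomic 3' trailer — the two extensions are
#' mutually exclusive per mature product.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param origin "N" (nuclear), "M" (mitochondrial) or "NM" (ambiguous).
#' @param sequence Gene-body nucleotide sequences (U converted to T).
#' @param loop_start,loop_end 1-based closed anticodon-loop interval.
#' @param introns List of 2-column integer matrices (start, end), one per
#'   gene; may be omitted for intron-less genes.
#' @param trailer Genomic 3' flank sequences (may be "").
#' @param cca_added Logical; whether the mature product carries appended CCA.
#'
#' @return A tibble of class `trf_gene_models`, one row per gene.
#' @export
gene_models <- function(gene_id, origin, sequence, loop_start, loop_end,
                        introns = NULL, trailer = "", cca_added = TRUE) {
  n <- length(gene_id)
  if (is.null(introns)) {
    introns <- replicate(n, parse_intron_field(""), simplify = FALSE)
  }
  tbl <- tibble::tibble(
    gene_id = as.character(gene_id),
    origin = rep_len(as.character(origin), n),
    sequence = normalise_sequence(rep_len(sequence, n)),
    loop_start = as.integer(rep_len(loop_start, n)),
    loop_end = as.integer(rep_len(loop_end, n)),
    introns = introns,
    trailer = normalise_sequence(rep_len(trailer, n)),
    cca_added = rep_len(as.logical(cca_added), n)
  )
  tbl <- validate_gene_models(tbl)
  class(tbl) <- c("trf_gene_models", class(tbl))
  tbl
}

#' Read tRNA gene models from an annotation TSV and a FASTA file
#'
#' The annotation is a plain TSV with one row per gene and columns
#' `gene_id`, `origin`, `loop_start`, `loop_end`, `introns` (comma-separated
#' `start-end` pairs, empty for none), `trailer`, `cca_added`. Sequences come
#' from the FASTA keyed by `gene_id`.
#'
#' @param annotation_file Path to the annotation TSV.
#' @param fasta_file Path to the gene-body FASTA.
#' @return A validated `trf_gene_models` tibble.
#' @export
read_gene_models <- function(annotation_file, fasta_file) {
  ann <- readr::read_tsv(annotation_file, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", origin = "c",
                           loop_start = "i", loop_end = "i",
                           introns = "c", trailer = "c", cca_added = "l"
                         ))
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  seq_map <- stats::setNames(as.character(seqs), names(seqs))
  missing <- setdiff(ann$gene_id, names(seq_map))
  if (length(missing)) {
    rlang::abort(paste("no sequence for gene_id:", paste(missing, collapse = ", ")),
                 class = "trf_missing_sequence")
  }
  ann$introns[is.na(ann$introns)] <- ""
  ann$trailer[is.na(ann$trailer)] <- ""
  gene_models(
    gene_id = ann$gene_id, origin = ann$origin,
    sequence = unname(seq_map[ann$gene_id]),
    loop_start = ann$loop_start, loop_end = ann$loop_end,
    introns = lapply(ann$introns, parse_intron_field),
    trailer = ann$trailer, cca_added = ann$cca_added
  )
}

#' Write tRNA gene models to an annotation TSV and FASTA
#'
#' Inverse of [read_gene_models()]; reading the written pair returns the
#' identical model table.
#'
#' @param models A `trf_gene_models` tibble.
#' @param annotation_file,fasta_file Output paths.
#' @return Invisibly, the input models.
#' @export
write_gene_models <- function(models, annotation_file, fasta_file) {
  ann <- tibble::tibble(
    gene_id = models$gene_id, origin = models$origin,
    loop_start = models$loop_start, loop_end = models$loop_end,
    introns = vapply(models$introns, format_intron_field, character(1)),
    trailer = models$trailer, cca_added = models$cca_added
  )
  readr::write_tsv(ann, annotation_file)
  seqs <- Biostrings::DNAStringSet(stats::setNames(models$sequence, models$gene_id))
  Biostrings::writeXStringSet(seqs, fasta_file)
  invisible(models)
}

#' Extended coordinate range of a mature tRNA product
#'
#' tRF coordinates live in an extended space: the gene body, optionally
#' followed by the appended CCA (for fragments from the mature 3' end) or by
#' the genomic 3' trailer (for trailer-derived fragments). CCA and trailer
#' are mutually exclusive.
#'
#' @param model One gene model (a one-row tibble or list with `sequence`,
#'   `trailer`).
#' @param product_kind One of "body", "body+CCA", "body+trailer".
#' @return Integer vector `c(1, max_coordinate)`.
#' @export
#' @examples
#' g <- gene_models("g1", "N", strrep("ACGT", 18), 33, 39, trailer = "ACGTT")
#' extended_coordinates(g[1, ], "body+CCA")    # 1 75
#' extended_coordinates(g[1, ], "body+trailer") # 1 77
extended_coordinates <- function(model, product_kind = c("body", "body+CCA", "body+trailer")) {
  product_kind <- match.arg(product_kind)
  L <- nchar(model$sequence[[1]])
  mx <- switch(product_kind,
    "body" = L,
    "body+CCA" = L + 3L,
    "body+trailer" = {
      tl <- nchar(model$trailer[[1]])
      if (tl == 0L) {
        rlang::abort("body+trailer requested but trailer is empty",
                     class = "trf_empty_trailer")
      }
      L + tl
    })
  c(1L, as.integer(mx))
}

# Sequence of a gene in one of the extended spaces.
extended_sequence <- function(sequence, trailer, space = c("body", "cca", "trailer")) {
  space <- match.arg(space)
  switch(space,
    body = sequence,
    cca = paste0(sequence, "CCA"),
    trailer = paste0(sequence, trailer))
}

#' Build a transcript-model table
#'
#' @param transcript_id Character vector of unique transcript ids.
#' @param category One of "mRNA", "rRNA", "miRNA", "other_ncRNA", "tRNA".
#' @param sequence Transcript sequences (U converted to T).
#' @param regions List of region tibbles (`region`, `start`, `end`) for mRNA
#'   entries; non-mRNA transcripts must have empty region tables.
#' @return A tibble of class `trf_transcript_models`.
#' @export
transcript_models <- function(transcript_id, category, sequence, regions = NULL) {
  n <- length(transcript_id)
  empty_regions <- tibble::tibble(region = character(0),
                                  start = integer(0), end = integer(0))
  if (is.null(regions)) regions <- replicate(n, empty_regions, simplify = FALSE)
  cats <- c("mRNA", "rRNA", "miRNA", "other_ncRNA", "tRNA")
  bad <- setdiff(unique(category), cats)
  if (length(bad)) rlang::abort(paste("unknown transcript category:", bad))
  tbl <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    category = rep_len(as.character(category), n),
    sequence = normalise_sequence(rep_len(sequence, n)),
    regions = regions
  )
  if (anyDuplicated(tbl$transcript_id)) {
    rlang::abort("duplicate transcript_id", class = "trf_duplicate_transcript")
  }
  for (i in seq_len(n)) {
    r <- tbl$regions[[i]]
    if (tbl$category[i] != "mRNA" && nrow(r) > 0L) {
      rlang::abort(paste0(tbl$transcript_id[i],
                          ": only mRNA transcripts carry region annotations"))
    }
    if (nrow(r)) {
      if (any(r$start < 1L) || any(r$end > nchar(tbl$sequence[i])) ||
          any(r$start > r$end)) {
        rlang::abort(paste0(tbl$transcript_id[i], ": region interval out of bounds"),
                     class = "trf_bad_interval")
      }
      bad_lab <- setdiff(unique(r$region), c("5UTR", "CDS", "3UTR", "intron"))
      if (length(bad_lab)) {
        rlang::abort(paste0(tbl$transcript_id[i], ": unknown region label ",
                            paste(bad_lab, collapse = ",")))
      }
    }
  }
  class(tbl) <- c("trf_transcript_models", class(tbl))
  tbl
}

#' Read transcript models from an annotation TSV and FASTA
#'
#' The TSV has one row per region — columns `transcript_id`, `category`,
#' `region`, `start`, `end` — with a single row carrying empty region fields
#' for transcripts without region annotation.
#'
#' @param annotation_file,fasta_file Input paths.
#' @return A `trf_transcript_models` tibble.
#' @export
read_transcript_models <- function(annotation_file, fasta_file) {
  ann <- readr::read_tsv(annotation_file, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = "c", category = "c",
                           region = "c", start = "i", end = "i"))
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  seq_map <- stats::setNames(as.character(seqs), names(seqs))
  ids <- unique(ann$transcript_id)
  missing <- setdiff(ids, names(seq_map))
  if (length(missing)) {
    rlang::abort(paste("no sequence for transcript_id:",
                       paste(missing, collapse = ", ")),
                 class = "trf_missing_sequence")
  }
  regions <- lapply(ids, function(id) {
    r <- ann[ann$transcript_id == id & !is.na(ann$region), c("region", "start", "end")]
    tibble::as_tibble(r)
  })
  transcript_models(
    transcript_id = ids,
    category = ann$category[match(ids, ann$transcript_id)],
    sequence = unname(seq_map[ids]),
    regions = regions
  )
}

#' Write transcript models to an annotation TSV and FASTA
#'
#' @param transcripts A `trf_transcript_models` tibble.
#' @param annotation_file,fasta_file Output paths.
#' @return Invisibly, the input.
#' @export
write_transcript_models <- function(transcripts, annotation_file, fasta_file) {
  rows <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    r <- transcripts$regions[[i]]
    if (nrow(r) == 0L) {
      tibble::tibble(transcript_id = transcripts$transcript_id[i],
                     category = transcripts$category[i],
                     region = NA_character_, start = NA_integer_, end = NA_integer_)
    } else {
      tibble::tibble(transcript_id = transcripts$transcript_id[i],
                     category = transcripts$category[i],
                     region = r$region, start = as.integer(r$start),
                     end = as.integer(r$end))
    }
  })
  readr::write_tsv(rows, annotation_file)
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(transcripts$sequence, transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_file)
  invisible(transcripts)
}
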