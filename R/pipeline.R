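collapse_list_col <- function(x) {
  vapply(x, function(v) paste(v, collapse = ","), character(1))
}

write_stage_tsv <- function(tbl, path) {
  for (nm in names(tbl)) if (is.list(tbl[[nm]])) tbl[[nm]] <- collapse_list_col(tbl[[nm]])
  readr::write_tsv(tbl, path)
  tibble::tibble(file = basename(path), rows = nrow(tbl),
                 md5 = unname(tools::md5sum(path)))
}

require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    rlang::abort(paste("missing stage input:", paste(missing, collapse = ", ")),
                 class = "trf_missing_input")
  }
}

# map per-gene conversion top sites onto guide coordinates
trf_top_sites <- function(profile_tops, trf_table) {
  purrr::map_dfr(seq_len(nrow(trf_table)), function(i) {
    row <- profile_tops[profile_tops$gene_id == trf_table$gene_id[i], ]
    if (nrow(row) == 0L || is.na(row$top_site[1])) {
      return(tibble::tibble(trf_name = trf_table$trf_name[i],
                            top_site = NA_integer_))
    }
    pos <- row$top_site[1] - trf_table$trf_start[i] + 1L
    len <- trf_table$trf_end[i] - trf_table$trf_start[i] + 1L
    tibble::tibble(trf_name = trf_table$trf_name[i],
                   top_site = if (pos >= 1L && pos <= len) as.integer(pos)
                              else NA_integer_)
  })
}

#' Run the full analysis pipeline on a synthetic workspace
#'
#' Orchestrates the stages — simulate, parse, classify, composition, motifs,
#' parclip, structure — reading every input from, and writing every output
#' to, plain text files under `out_dir`, and records a manifest (file, row
#' count, md5) per output. Identical config and seed give byte-identical
#' manifests.
#'
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param out_dir Output directory.
#' @param stages Subset of stages to run (later stages require the files of
#'   earlier ones; a missing input fails with the offending path).
#' @param thresholds A [trf_thresholds()] record.
#' @param motif_params List of motif-stage knobs: `width_range`, `n_decoys`,
#'   `n_starts`, `max_trfs` (cap on the number of guides sent to discovery).
#' @return List with `manifest` (tibble: stage, file, rows, md5, config_hash,
#'   seed) and `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config = simulation_config(),
                         out_dir = tempfile("trfclash_run_"),
                         stages = c("simulate", "parse", "classify",
                                    "composition", "motifs", "parclip",
                                    "structure"),
                         thresholds = trf_thresholds(),
                         motif_params = list(width_range = 6:10,
                                             n_decoys = 10L, n_starts = 2L,
                                             max_trfs = 6L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- file.path(out_dir, "inputs")
  manifest <- list(); results <- list()
  add <- function(stage, entry) {
    entry$stage <- stage
    manifest[[length(manifest) + 1L]] <<- entry
  }
  f_in <- function(x) file.path(inputs, x)
  f_out <- function(x) file.path(out_dir, x)

  if ("simulate" %in% stages) {
    ws <- simulate_workspace(config, inputs)
    results$workspace <- ws
    for (p in ws$files) {
      add("simulate", tibble::tibble(file = basename(p),
                                     rows = NA_integer_,
                                     md5 = unname(tools::md5sum(p))))
    }
  }

  if ("parse" %in% stages) {
    require_inputs(f_in(c("genes.tsv", "genes.fa", "transcripts.tsv",
                          "transcripts.fa", "clash_reads.fa")))
    genes <- read_gene_models(f_in("genes.tsv"), f_in("genes.fa"))
    transcripts <- read_transcript_models(f_in("transcripts.tsv"),
                                          f_in("transcripts.fa"))
    reads <- read_sequences(f_in("clash_reads.fa"))
    index <- build_gene_index(genes)
    parsed <- split_reads(reads, index, transcripts, "both", thresholds)
    tallies <- tally_pairs(parsed$decompositions)
    results$parsed <- parsed; results$tallies <- tallies
    results$genes <- genes; results$transcripts <- transcripts
    add("parse", write_stage_tsv(parsed$decompositions, f_out("decompositions.tsv")))
    add("parse", write_stage_tsv(parsed$rejections, f_out("rejections.tsv")))
    add("parse", write_stage_tsv(parsed$trf_trf, f_out("trf_trf.tsv")))
    add("parse", write_stage_tsv(tallies$pairs, f_out("pairs.tsv")))
    add("parse", write_stage_tsv(tallies$summary, f_out("pair_summary.tsv")))
  }

  if ("classify" %in% stages) {
    d <- results$parsed$decompositions
    ld <- length_distribution(d)
    fwd <- dplyr::count(d[d$orientation == "forward", ], .data$trf_name)
    rev <- dplyr::count(d[d$orientation == "reverse", ], .data$trf_name)
    names(fwd) <- names(rev) <- c("name", "count")
    cmp <- compare_orientations(fwd, rev, "isoform")
    results$length_distribution <- ld
    results$orientation_comparison <- cmp
    add("classify", write_stage_tsv(ld, f_out("length_distribution.tsv")))
    add("classify", write_stage_tsv(
      dplyr::mutate(cmp$table, pearson_r = cmp$pearson_r),
      f_out("orientation_comparison.tsv")))
  }

  if ("composition" %in% stages) {
    d <- results$parsed$decompositions
    vec <- dinucleotide_vectors(d$target_seq, d$read_id)
    pca <- pca_project(vec)
    part <- partition_by_polyt(d, thresholds)
    scores <- dplyr::bind_cols(
      pca$scores,
      tibble::tibble(orientation = d$orientation,
                     has_polyt_run = d$read_id %in% part$polyt$read_id))
    results$pca <- pca; results$polyt_partition <- part
    add("composition", write_stage_tsv(scores, f_out("pca_scores.tsv")))
    add("composition", write_stage_tsv(part$contrast, f_out("polyt_contrast.tsv")))
  }

  if ("motifs" %in% stages) {
    pairs <- results$tallies$pairs
    keep <- pairs[!polyt_report(pairs$target_seq, thresholds = thresholds)$has_polyt_run, ]
    counts <- dplyr::count(keep, .data$trf_name, wt = NULL, sort = TRUE)
    trf_names <- utils::head(counts$trf_name[counts$n >= thresholds$min_motif_targets],
                             motif_params$max_trfs)
    d <- results$parsed$decompositions
    trf_seqs <- d[!duplicated(d$trf_name), c("trf_name", "trf_seq")]
    motif_rows <- list(); comparisons <- list(); motif_objects <- list()
    for (tn in trf_names) {
      sub <- pairs[pairs$trf_name == tn, ]
      seqd <- trf_seqs$trf_seq[trf_seqs$trf_name == tn]
      per_ori <- list()
      for (ori in c("forward", "reverse")) {
        ts <- assemble_target_set(sub[sub$orientation == ori, ], thresholds)
        per_ori[[ori]] <- ts
        if (ts$status != "ok") next
        m <- discover_motif(ts$targets, width_range = motif_params$width_range,
                            seed = config$seed + 10L, thresholds = thresholds,
                            n_decoys = motif_params$n_decoys,
                            n_starts = motif_params$n_starts)
        if (is.null(m)) next
        m$orientation <- ori
        m <- match_back(m, seqd, trf_name = tn, thresholds = thresholds)
        motif_objects[[paste(tn, ori)]] <- m
        motif_rows[[length(motif_rows) + 1L]] <- glance.trf_pwm(m)
      }
      fwd <- motif_objects[[paste(tn, "forward")]]
      rev <- motif_objects[[paste(tn, "reverse")]]
      if (!is.null(fwd) || !is.null(rev)) {
        comparisons[[length(comparisons) + 1L]] <- compare_motifs(fwd, rev, tn)
      }
      pooled <- tryCatch(
        combine_orientations(per_ori$forward$targets, per_ori$reverse$targets,
                             thresholds, seed = config$seed + 11L,
                             width_range = motif_params$width_range,
                             n_decoys = motif_params$n_decoys,
                             n_starts = motif_params$n_starts),
        trf_insufficient_targets = function(e) NULL)
      if (!is.null(pooled)) {
        pooled <- match_back(pooled, seqd, trf_name = tn, thresholds = thresholds)
        motif_objects[[paste(tn, "combined")]] <- pooled
        motif_rows[[length(motif_rows) + 1L]] <- glance.trf_pwm(pooled)
      }
    }
    motif_tbl <- dplyr::bind_rows(motif_rows)
    cmp_tbl <- dplyr::bind_rows(comparisons)
    results$motifs <- motif_objects
    results$motif_table <- motif_tbl
    results$motif_comparisons <- cmp_tbl
    if (nrow(motif_tbl) >= 3L) {
      results$ranked_motifs <- rank_motifs(motif_tbl)
      add("motifs", write_stage_tsv(results$ranked_motifs, f_out("ranked_motifs.tsv")))
    }
    ud <- tryCatch(upstream_downstream_test(cmp_tbl),
                   trf_empty_input = function(e) NULL, error = function(e) NULL)
    results$upstream_downstream <- ud
    add("motifs", write_stage_tsv(motif_tbl, f_out("motifs.tsv")))
    add("motifs", write_stage_tsv(cmp_tbl, f_out("motif_comparisons.tsv")))
    mdir <- f_out("motif_matrices")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(motif_objects)) {
      p <- file.path(mdir, paste0(gsub("[^A-Za-z0-9_-]", "_", nm), ".txt"))
      write_motif_matrix(motif_objects[[nm]], p)
      add("motifs", tibble::tibble(file = file.path("motif_matrices", basename(p)),
                                   rows = NA_integer_,
                                   md5 = unname(tools::md5sum(p))))
    }
  }

  if ("parclip" %in% stages) {
    require_inputs(f_in(c("parclip_reads.fa", "parclip_samples.tsv")))
    x <- Biostrings::readDNAStringSet(f_in("parclip_reads.fa"))
    reads <- tibble::tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sample = sub("^\\S+\\s+", "", names(x)),
      sequence = as.character(x))
    totals_tbl <- readr::read_tsv(f_in("parclip_samples.tsv"),
                                  show_col_types = FALSE)
    totals <- stats::setNames(totals_tbl$total, totals_tbl$sample)
    aln <- align_parclip_reads(reads, results$genes, thresholds)
    prof <- conversion_profile(aln$alignments, totals)
    results$parclip_alignments <- aln
    results$conversion_profile <- prof
    add("parclip", write_stage_tsv(prof$profile, f_out("conversion_profile.tsv")))
    add("parclip", write_stage_tsv(prof$top_sites, f_out("conversion_top_sites.tsv")))
    motifs <- results$motifs
    if (length(motifs)) {
      d <- results$parsed$decompositions
      trf_table <- d[!duplicated(d$trf_name),
                     c("trf_name", "gene_id", "trf_start", "trf_end")]
      tops <- trf_top_sites(prof$top_sites, trf_table)
      hist <- bitscore_histogram(motifs, tops)
      results$bitscore <- hist
      results$side_bias <- tryCatch(side_bias_test(hist),
                                    trf_empty_input = function(e) NULL)
      add("parclip", write_stage_tsv(hist$histogram, f_out("bitscore_histogram.tsv")))
      add("parclip", write_stage_tsv(hist$per_trf, f_out("bitscore_per_trf.tsv")))
    }
  }

  if ("structure" %in% stages) {
    require_inputs(f_in("reactivity.tsv"))
    track <- read_reactivity_track(f_in("reactivity.tsv"))
    motifs <- results$motifs
    pairs <- results$tallies$pairs
    sites <- list()
    for (nm in names(motifs)) {
      m <- motifs[[nm]]
      if (is.na(m$orientation) || m$orientation == "combined") next
      sub <- pairs[pairs$trf_name == m$trf_name &
                     pairs$orientation == m$orientation &
                     pairs$category == "mRNA", ]
      for (i in seq_len(nrow(sub))) {
        if (nchar(sub$target_seq[i]) < m$width) next
        hit <- pwm_match_pvalue(m$matrix, sub$target_seq[i], revcomp_scan = FALSE)
        sites[[length(sites) + 1L]] <- tibble::tibble(
          transcript_id = sub$transcript_id[i],
          start = sub$tx_start[i] + hit$trf_interval[1] - 1L,
          end = sub$tx_start[i] + hit$trf_interval[2] - 1L)
      }
    }
    sites <- dplyr::distinct(dplyr::bind_rows(sites))
    if (nrow(sites)) {
      scored <- collect_site_scores(sites, track, flank = 20L, thresholds)
      prof <- aligned_profile(scored)
      results$reactivity_sites <- scored
      results$reactivity_profile <- prof
      results$ds_fraction <- ds_fraction(scored)
      sig <- tryCatch(
        significance_vs_random(scored, track,
                               width = thresholds$random_kmer_width,
                               n_draws = 500L, seed = config$seed + 12L),
        error = function(e) NULL)
      results$reactivity_significance <- sig
      add("structure", write_stage_tsv(
        dplyr::select(scored, -"scores"), f_out("reactivity_sites.tsv")))
      add("structure", write_stage_tsv(prof, f_out("reactivity_profile.tsv")))
      if (!is.null(sig)) {
        add("structure", write_stage_tsv(sig, f_out("reactivity_significance.tsv")))
      }
    }
  }

  manifest <- dplyr::bind_rows(manifest)
  manifest$config_hash <- rlang::hash(unclass(config))
  manifest$seed <- config$seed
  manifest <- manifest[, c("stage", "file", "rows", "md5", "config_hash", "seed")]
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  list(manifest = manifest, results = results, out_dir = out_dir)
}
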