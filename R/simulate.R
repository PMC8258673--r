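#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults encode the study
#' conditions the pipeline is designed around: guide lengths with an 18 nt
#' mode for 3'-end fragments and 33–36 nt 5' halves ending in the anticodon
#' loop; crosslinking hotspots at guide positions 8–12 with a 0.3 conversion
#' rate over a 0.01 background; an orientation mechanism in which each
#' guide's binding region falls 5' (upstream) of its crosslinking site with
#' probability `upstream_prob`, upstream binders produce forward chimeras
#' with probability `forward_given_upstream`, and 5' halves have their
#' forward-ligation odds scaled by `1 - cyclic_phosphate_penalty` (the
#' 2',3'-cyclic phosphate mechanism); polyT artifacts appended to forward
#' targets; and target sites double-stranded with probability
#' `ds_probability` and reactivity shifted by `reactivity_delta`.
#'
#' @param seed Base seed; every generator stage derives its own stream from
#'   it and identical configs give byte-identical outputs.
#' @param n_genes,gene_length_range,loop_length,loop_start_range,trailer_length_range,intron_prob
#'   tRNA gene geometry.
#' @param n_transcripts Named counts per category (mRNA, rRNA, miRNA,
#'   other_ncRNA).
#' @param transcript_length_range Transcript length bounds (nt).
#' @param trfs_per_gene,trf_type_probs Planted guide mix.
#' @param motif_width,site_identity,sites_per_trf Planted motif geometry:
#'   width, per-position identity of target sites, distinct sites per guide.
#' @param upstream_prob,forward_given_upstream,cyclic_phosphate_penalty
#'   Orientation mechanism (see above).
#' @param polyt_site_rate,polyt_run_range polyT artifact rate over planted
#'   sites and appended run length bounds.
#' @param n_clash_reads,trf_trf_fraction,pure_trna_fraction Chimeric read
#'   counts and injected negative-control fractions.
#' @param n_parclip_reads,n_parclip_samples,parclip_short_fraction,hotspot_range,conversion_rate,background_conversion_rate
#'   PAR-CLIP read simulation.
#' @param reactivity_delta,ds_probability,reactivity_na_rate Reactivity track
#'   simulation.
#' @return A list of class `trf_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 6L,
                              gene_length_range = c(72L, 78L),
                              loop_length = 7L,
                              loop_start_range = c(31L, 33L),
                              trailer_length_range = c(10L, 15L),
                              intron_prob = 0.2,
                              n_transcripts = c(mRNA = 15L, rRNA = 2L,
                                                miRNA = 2L, other_ncRNA = 2L),
                              transcript_length_range = c(450L, 700L),
                              trfs_per_gene = 2L,
                              trf_type_probs = c("3p" = 0.35, "5i" = 0.15,
                                                 "5p" = 0.15, "3t" = 0.15,
                                                 "i" = 0.15, "3i" = 0.05),
                              motif_width = 8L,
                              site_identity = 0.9,
                              sites_per_trf = 15L,
                              upstream_prob = 0.8,
                              forward_given_upstream = 0.8,
                              cyclic_phosphate_penalty = 0.5,
                              polyt_site_rate = 0.1,
                              polyt_run_range = c(5L, 8L),
                              n_clash_reads = 2000L,
                              trf_trf_fraction = 0.05,
                              pure_trna_fraction = 0.05,
                              n_parclip_reads = 4000L,
                              n_parclip_samples = 3L,
                              parclip_short_fraction = 0.1,
                              hotspot_range = 8:12,
                              conversion_rate = 0.3,
                              background_conversion_rate = 0.01,
                              reactivity_delta = 0.3,
                              ds_probability = 0.983,
                              reactivity_na_rate = 0.02) {
  cfg <- as.list(environment())
  probs <- c(cfg$upstream_prob, cfg$forward_given_upstream,
             cfg$cyclic_phosphate_penalty, cfg$polyt_site_rate,
             cfg$site_identity, cfg$conversion_rate,
             cfg$background_conversion_rate, cfg$ds_probability,
             cfg$reactivity_na_rate, cfg$trf_trf_fraction,
             cfg$pure_trna_fraction, cfg$parclip_short_fraction)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("all probabilities must lie in [0, 1]",
                 class = "trf_bad_config")
  }
  structure(cfg, class = c("trf_sim_config", "list"))
}

rand_seq <- function(n, bases = BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# break homopolymer runs of `base` at length >= k by substituting `sub`
break_runs <- function(sequence, base = "T", k = 5L, sub = "C") {
  pat <- paste0(base, "{", k, ",}")
  stringr::str_replace_all(sequence, pat, function(run) {
    s <- strsplit(run, "")[[1]]
    s[seq(k, length(s), by = k)] <- sub
    paste(s, collapse = "")
  })
}

mutate_site <- function(site, identity) {
  s <- strsplit(site, "")[[1]]
  flip <- stats::runif(length(s)) > identity
  s[flip] <- vapply(s[flip], function(b) sample(setdiff(BASES, b), 1),
                    character(1))
  paste(s, collapse = "")
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

plant_trf <- function(model, cfg) {
  L <- nchar(model$sequence)
  ls <- model$loop_start; le <- model$loop_end
  type <- sample(names(cfg$trf_type_probs), 1, prob = cfg$trf_type_probs)
  tl <- nchar(model$trailer)
  coords <- switch(type,
    "5p" = {
      st <- sample1(1:2)
      len <- sample1(16:min(19L, ls - st))
      list(start = st, end = st + len - 1L, space = "body")
    },
    "5i" = {
      end <- sample1(max(33L, ls):min(36L, le))
      list(start = 1L, end = end, space = "body")
    },
    "3p" = {
      len <- sample(16:22, 1, prob = c(2, 4, 8, 4, 2, 1, 1))
      list(start = L + 4L - len, end = L + 3L, space = "cca")
    },
    "3i" = {
      st <- sample1(ls:le)
      list(start = st, end = sample1((L - 1L):(L + 3L)), space = "cca")
    },
    "3t" = {
      end <- L + 3L + sample1(0:(tl - 3L))
      len <- sample1(18:22)
      list(start = end - len + 1L, end = end, space = "trailer")
    },
    "i" = {
      len <- sample1(16:20)
      st <- sample1(6:(L - 2L - len + 1L))
      list(start = st, end = st + len - 1L, space = "body")
    })
  c(list(type = type), coords)
}

#' Generate synthetic tRNA gene models and a transcriptome with planted truth
#'
#' Builds random tRNA gene models (anticodon loops positioned so planted 5'
#' halves of 33–36 nt end inside the loop), plants a set of guides (tRFs)
#' with per-guide crosslinking hotspots (the reference base is forced to T)
#' and binding motifs placed 5' or 3' of the hotspot according to the
#' orientation mechanism, and embeds noisy complementary copies of each
#' guide's motif region into mRNA transcripts as target sites. Chance T-runs
#' of 5+ nt are broken in transcript backgrounds so that planted polyT
#' artifact runs are the only ones present.
#'
#' @param config A [simulation_config()].
#' @return List of class `trf_references`: `genes`, `transcripts`, `trfs`
#'   (planted guide truth, including the planted motif matrix), `sites`
#'   (planted target-site truth).
#' @export
make_references <- function(config) {
  cfg <- config
  w <- cfg$motif_width
  withr::with_seed(cfg$seed, {
    # --- genes -----------------------------------------------------------
    gene_ids <- sprintf("Syn%s-%03d",
                        sample(c("AlaAGC", "CysGCA", "GluCTC", "GlyGCC",
                                 "LeuTAA", "ThrAGT", "IleTAT", "LysCTT",
                                 "ValAAC", "SerGCT"),
                               cfg$n_genes, replace = TRUE),
                        seq_len(cfg$n_genes))
    genes_raw <- purrr::map(seq_len(cfg$n_genes), function(i) {
      L <- sample1(cfg$gene_length_range[1]:cfg$gene_length_range[2])
      sq <- break_runs(break_runs(rand_seq(L), "T", 5L, "C"), "A", 4L, "G")
      ls <- sample1(cfg$loop_start_range[1]:cfg$loop_start_range[2])
      introns <- if (stats::runif(1) < cfg$intron_prob) {
        st <- sample1((ls + cfg$loop_length + 2L):(L - 14L))
        matrix(c(st, st + sample1(6:9)), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
      } else {
        matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
      }
      tl <- sample1(cfg$trailer_length_range[1]:cfg$trailer_length_range[2])
      trailer <- break_runs(break_runs(rand_seq(tl), "T", 5L, "C"), "A", 4L, "G")
      list(gene_id = gene_ids[i], sequence = sq, loop_start = ls,
           loop_end = ls + cfg$loop_length - 1L, introns = introns,
           trailer = trailer)
    })

    # --- planted guides --------------------------------------------------
    trf_rows <- list()
    for (gi in seq_len(cfg$n_genes)) {
      g <- genes_raw[[gi]]
      for (k in seq_len(cfg$trfs_per_gene)) {
        p <- plant_trf(g, cfg)
        len <- p$end - p$start + 1L
        hs <- sample1(cfg$hotspot_range[cfg$hotspot_range <= len - 2L])
        side <- if (stats::runif(1) < cfg$upstream_prob) "upstream" else "downstream"
        if (side == "upstream") {
          ms <- max(1L, hs - w)
        } else {
          ms <- min(hs + 1L, len - w + 1L)
        }
        trf_rows[[length(trf_rows) + 1L]] <- tibble::tibble(
          gene_index = gi, gene_id = g$gene_id, type = p$type,
          start = p$start, end = p$end, space = p$space, length = len,
          hotspot = hs, motif_start = ms, motif_end = ms + w - 1L,
          side = side
        )
      }
    }
    trfs <- dplyr::bind_rows(trf_rows)
    trfs <- trfs[!duplicated(trfs[, c("gene_id", "type", "start", "end")]), ]
    trfs$trf_id <- sprintf("trf%03d", seq_len(nrow(trfs)))

    # force the reference base at each hotspot to T (gene-body coordinate)
    for (i in seq_len(nrow(trfs))) {
      gi <- trfs$gene_index[i]
      gp <- trfs$start[i] + trfs$hotspot[i] - 1L
      g <- genes_raw[[gi]]
      full <- paste0(g$sequence, g$trailer)
      substr(full, gp, gp) <- "T"
      genes_raw[[gi]]$sequence <- substr(full, 1L, nchar(g$sequence))
      genes_raw[[gi]]$trailer <- substr(full, nchar(g$sequence) + 1L, nchar(full))
    }

    genes <- gene_models(
      gene_id = vapply(genes_raw, `[[`, character(1), "gene_id"),
      origin = "N",
      sequence = vapply(genes_raw, `[[`, character(1), "sequence"),
      loop_start = vapply(genes_raw, `[[`, integer(1), "loop_start"),
      loop_end = vapply(genes_raw, `[[`, integer(1), "loop_end"),
      introns = lapply(genes_raw, `[[`, "introns"),
      trailer = vapply(genes_raw, `[[`, character(1), "trailer"),
      cca_added = TRUE
    )

    # guide sequences and canonical names from the final gene sequences
    trfs$sequence <- vapply(seq_len(nrow(trfs)), function(i) {
      g <- genes[genes$gene_id == trfs$gene_id[i], ]
      substr(extended_sequence(g$sequence, g$trailer, trfs$space[i]),
             trfs$start[i], trfs$end[i])
    }, character(1))
    trfs$trf_name <- trf_name(trfs$gene_id, "N", trfs$type, trfs$start, trfs$end)
    # planted target PWM: complementary match to the guide's motif region
    trfs$motif_matrix <- lapply(seq_len(nrow(trfs)), function(i) {
      site <- revcomp(substr(trfs$sequence[i], trfs$motif_start[i],
                             trfs$motif_end[i]))
      m <- matrix((1 - cfg$site_identity) / 3, nrow = 4, ncol = w,
                  dimnames = list(BASES, NULL))
      m[cbind(match(strsplit(site, "")[[1]], BASES), seq_len(w))] <- cfg$site_identity
      m
    })

    # --- transcripts -----------------------------------------------------
    n_tx <- cfg$n_transcripts
    tx_ids <- unname(unlist(purrr::imap(as.list(n_tx), function(n, cat) {
      if (n == 0L) character(0) else sprintf("%s_%02d", cat, seq_len(n))
    })))
    tx_cat <- rep(names(n_tx), n_tx)
    tx_len <- if (length(tx_ids)) {
      vapply(tx_ids, function(x) {
        sample1(cfg$transcript_length_range[1]:cfg$transcript_length_range[2])
      }, integer(1))
    } else integer(0)
    tx_seq <- vapply(tx_len, function(L) break_runs(rand_seq(L), "T", 5L, "C"),
                     character(1))

    # --- embed target sites into mRNA transcripts ------------------------
    sites <- tibble::tibble(site_id = character(0), trf_id = character(0),
                            transcript_id = character(0),
                            site_start = integer(0), site_end = integer(0),
                            artifact = logical(0), run_len = integer(0))
    mrna_idx <- which(tx_cat == "mRNA")
    if (nrow(trfs) > 0 && cfg$sites_per_trf > 0 && length(mrna_idx) > 0) {
      stride <- w + 28L
      slots <- purrr::map_dfr(mrna_idx, function(j) {
        n_slots <- (tx_len[j] - 30L) %/% stride
        if (n_slots < 1L) return(NULL)
        tibble::tibble(tx = j, pos = 16L + (seq_len(n_slots) - 1L) * stride)
      })
      need <- nrow(trfs) * cfg$sites_per_trf
      if (nrow(slots) < need) {
        rlang::abort(sprintf(
          "transcriptome too small for %d planted sites (capacity %d)",
          need, nrow(slots)), class = "trf_bad_config")
      }
      slots <- slots[sample.int(nrow(slots)), ][seq_len(need), ]
      site_rows <- list()
      k <- 0L
      for (i in seq_len(nrow(trfs))) {
        core <- revcomp(substr(trfs$sequence[i], trfs$motif_start[i],
                               trfs$motif_end[i]))
        for (s in seq_len(cfg$sites_per_trf)) {
          k <- k + 1L
          planted <- mutate_site(core, cfg$site_identity)
          planted <- break_runs(planted, "T", 5L, "C")
          j <- slots$tx[k]; p <- slots$pos[k]
          substr(tx_seq[j], p, p + w - 1L) <- planted
          site_rows[[k]] <- tibble::tibble(
            site_id = sprintf("site%04d", k), trf_id = trfs$trf_id[i],
            transcript_id = tx_ids[j], site_start = p,
            site_end = p + w - 1L, artifact = FALSE, run_len = 0L)
        }
      }
      sites <- dplyr::bind_rows(site_rows)
      # background cleanup, then plant the polyT artifact runs
      tx_seq <- vapply(tx_seq, break_runs, character(1), USE.NAMES = FALSE)
      art <- stats::runif(nrow(sites)) < cfg$polyt_site_rate
      for (k in which(art)) {
        rl <- sample1(cfg$polyt_run_range[1]:cfg$polyt_run_range[2])
        j <- match(sites$transcript_id[k], tx_ids)
        substr(tx_seq[j], sites$site_end[k] + 1L, sites$site_end[k] + rl) <-
          strrep("T", rl)
        sites$artifact[k] <- TRUE
        sites$run_len[k] <- rl
      }
    }

    transcripts <- if (length(tx_ids)) {
      transcript_models(
        transcript_id = tx_ids, category = tx_cat, sequence = unname(tx_seq),
        regions = purrr::map(seq_along(tx_ids), function(j) {
          if (tx_cat[j] != "mRNA") {
            return(tibble::tibble(region = character(0), start = integer(0),
                                  end = integer(0)))
          }
          L <- tx_len[j]
          tibble::tibble(region = c("5UTR", "CDS", "3UTR"),
                         start = c(1L, 51L, L - 99L),
                         end = c(50L, L - 100L, L))
        })
      )
    } else {
      transcript_models(character(0), character(0), character(0))
    }

    structure(list(genes = genes, transcripts = transcripts,
                   trfs = trfs, sites = sites, config = cfg),
              class = "trf_references")
  })
}

#' Planted motifs as fitted-motif objects, plus planted hotspot table
#'
#' Converts the generator's per-guide truth (planted complementary PWM, its
#' guide interval, the crosslinking hotspot) into `trf_pwm` objects and a
#' `top_sites` tibble, directly usable by [bitscore_histogram()] and
#' [side_bias_test()].
#'
#' @param references A `trf_references` object.
#' @return List with `motifs` (list of `trf_pwm`) and `top_sites` (tibble).
#' @export
planted_motif_objects <- function(references) {
  trfs <- references$trfs
  motifs <- purrr::map(seq_len(nrow(trfs)), function(i) {
    new_trf_pwm(
      matrix = trfs$motif_matrix[[i]],
      width = trfs$motif_end[i] - trfs$motif_start[i] + 1L,
      e_value = NA_real_, score = NA_real_,
      n_sites = references$config$sites_per_trf,
      n_targets = references$config$sites_per_trf, read_support = NA_real_,
      trf_name = trfs$trf_name[i],
      trf_interval = c(trfs$motif_start[i], trfs$motif_end[i])
    )
  })
  list(motifs = motifs,
       top_sites = tibble::tibble(trf_name = trfs$trf_name,
                                  top_site = trfs$hotspot))
}

# pick a flank length in [lo, hi] whose transcript base differs from `avoid`
# (prevents the greedy anchored arm from extending past the planted guide)
pick_flank <- function(tx_seq, boundary, dir, lo, hi, avoid) {
  for (l in lo:hi) {
    pos <- if (dir < 0) boundary - l else boundary + l
    if (pos < 1L || pos > nchar(tx_seq)) next
    if (is.na(avoid) || substr(tx_seq, pos, pos) != avoid) return(l)
  }
  NA_integer_
}

#' Simulate chimeric CLASH-style reads with planted truth
#'
#' For each read a planted target site is drawn; its guide's binding side and
#' type set the orientation: upstream binders emit forward chimeras with
#' probability `forward_given_upstream` (downstream binders with the
#' complementary probability), and 5' halves (type 5i) have their forward
#' odds scaled by `1 - cyclic_phosphate_penalty`. The target arm is an exact
#' transcript substring covering the planted site; polyT-artifact sites emit
#' forward reads whose target arm ends in the planted T-run. Negative
#' controls — guide–guide chimeras (different genes and same-gene disjoint)
#' and pure-tRNA reads — are injected at the configured fractions.
#'
#' @param config A [simulation_config()].
#' @param references Matching [make_references()] output.
#' @return List with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (one row per read).
#' @export
simulate_clash_reads <- function(config, references) {
  cfg <- config
  genes <- references$genes
  trfs <- references$trfs
  sites <- references$sites
  tx <- references$transcripts
  tx_seq <- stats::setNames(tx$sequence, tx$transcript_id)
  gene_ext <- stats::setNames(
    purrr::map_chr(seq_len(nrow(genes)), function(i) {
      paste0(genes$sequence[i], genes$trailer[i])
    }), genes$gene_id)
  odds_scale <- 1 - cfg$cyclic_phosphate_penalty
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_clash_reads
    n_tt <- round(n * cfg$trf_trf_fraction)
    n_pure <- round(n * cfg$pure_trna_fraction)
    n_pair <- n - n_tt - n_pure
    rows <- list(); reads <- character(n); kinds <- character(n)
    truth <- list()
    for (r in seq_len(n_pair)) {
      si <- sample.int(nrow(sites), 1L)
      st <- sites[si, ]
      ti <- match(st$trf_id, trfs$trf_id)
      tr <- trfs[ti, ]
      g <- genes[genes$gene_id == tr$gene_id, ]
      space_seq <- extended_sequence(g$sequence, g$trailer, tr$space)
      p_up <- if (tr$side == "upstream") cfg$forward_given_upstream
              else 1 - cfg$forward_given_upstream
      if (tr$type == "5i") {
        o <- p_up / (1 - p_up) * odds_scale
        p_up <- o / (1 + o)
      }
      orientation <- if (st$artifact) "forward"
                     else if (stats::runif(1) < p_up) "forward" else "reverse"
      seqtx <- tx_seq[[st$transcript_id]]
      min_target <- max(12L, floor(tr$length / 4) + 1L)
      extra <- max(0L, min_target - (cfg$motif_width + 4L))
      lo <- 2L + ceiling(extra / 2)
      if (orientation == "forward") {
        # arm may not extend past the guide's 3' end into the target
        avoid <- if (tr$end < nchar(space_seq)) {
          substr(space_seq, tr$end + 1L, tr$end + 1L)
        } else NA_character_
        l5 <- pick_flank(seqtx, st$site_start, -1L, lo, 12L, avoid)
        l3 <- if (st$artifact) st$run_len else sample1(lo:12L)
      } else {
        avoid <- if (tr$start > 1L) {
          substr(space_seq, tr$start - 1L, tr$start - 1L)
        } else NA_character_
        l3 <- pick_flank(seqtx, st$site_end, +1L, lo, 12L, avoid)
        l5 <- sample1(lo:12L)
      }
      if (is.na(l5) || is.na(l3)) { # pathological context; emit pure-tRNA read
        reads[r] <- substr(gene_ext[[tr$gene_id]], 1L, 30L)
        kinds[r] <- "pure_trna"
        truth[[r]] <- tibble::tibble(read_id = sprintf("read%05d", r),
                                     kind = "pure_trna")
        next
      }
      t_start <- st$site_start - l5
      t_end <- st$site_end + l3
      target <- substr(seqtx, t_start, t_end)
      reads[r] <- if (orientation == "forward") paste0(tr$sequence, target)
                  else paste0(target, tr$sequence)
      kinds[r] <- "pair"
      truth[[r]] <- tibble::tibble(
        read_id = sprintf("read%05d", r), kind = "pair",
        orientation = orientation, trf_id = tr$trf_id,
        trf_name = tr$trf_name, trf_type = tr$type, gene_id = tr$gene_id,
        transcript_id = st$transcript_id, site_id = st$site_id,
        target_start = t_start, target_end = t_end, target_seq = target,
        artifact = st$artifact)
    }
    for (r in seq_len(n_tt)) {
      idx <- n_pair + r
      if (r %% 2L == 1L && nrow(genes) >= 2L) {
        pick <- sample.int(nrow(trfs), 2L)
        while (trfs$gene_id[pick[1]] == trfs$gene_id[pick[2]]) {
          pick <- sample.int(nrow(trfs), 2L)
        }
        reads[idx] <- paste0(trfs$sequence[pick[1]], trfs$sequence[pick[2]])
        cls <- "different_gene_pair"
      } else {
        gi <- sample.int(nrow(genes), 1L)
        sq <- genes$sequence[gi]
        reads[idx] <- paste0(substr(sq, 1L, 18L),
                             substr(sq, nchar(sq) - 19L, nchar(sq)))
        cls <- "same_gene_disjoint"
      }
      kinds[idx] <- "trf_trf"
      truth[[idx]] <- tibble::tibble(read_id = sprintf("read%05d", idx),
                                     kind = "trf_trf", classification = cls)
    }
    for (r in seq_len(n_pure)) {
      idx <- n_pair + n_tt + r
      gi <- sample.int(nrow(genes), 1L)
      len <- sample1(24:40)
      stp <- sample1(1:(nchar(genes$sequence[gi]) - len + 1L))
      reads[idx] <- substr(genes$sequence[gi], stp, stp + len - 1L)
      kinds[idx] <- "pure_trna"
      truth[[idx]] <- tibble::tibble(read_id = sprintf("read%05d", idx),
                                     kind = "pure_trna")
    }
    list(
      reads = tibble::tibble(read_id = sprintf("read%05d", seq_len(n)),
                             sequence = reads),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Simulate PAR-CLIP reads over the planted guides
#'
#' Reads copy planted guide sequences; the hotspot T converts to C at
#' `conversion_rate`, otherwise one random other T converts at
#' `background_conversion_rate` (at most one conversion per read, so every
#' full-length read aligns). A `parclip_short_fraction` of reads is truncated
#' below the 16 nt filter to exercise it. Per-sample totals count the emitted
#' full-length (alignable) reads.
#'
#' @param config A [simulation_config()].
#' @param references Matching [make_references()] output.
#' @return List with `reads` (tibble `read_id`, `sequence`, `sample`),
#'   `sample_totals` (named vector), `truth` (per-read tibble).
#' @export
simulate_parclip_reads <- function(config, references) {
  cfg <- config
  trfs <- references$trfs
  bad <- substr(trfs$sequence, trfs$hotspot, trfs$hotspot) != "T"
  if (any(bad)) {
    rlang::abort(paste("hotspot base is not T for",
                       paste(trfs$trf_name[bad], collapse = ", ")),
                 class = "trf_bad_config")
  }
  # T positions available for background conversions, per guide
  t_pos <- lapply(seq_len(nrow(trfs)), function(i) {
    setdiff(which(strsplit(trfs$sequence[i], "")[[1]] == "T"),
            trfs$hotspot[i])
  })
  withr::with_seed(cfg$seed + 2L, {
    n <- cfg$n_parclip_reads
    samples <- sprintf("sample%d", sample.int(cfg$n_parclip_samples, n,
                                              replace = TRUE))
    ti <- sample.int(nrow(trfs), n, replace = TRUE)
    short <- stats::runif(n) < cfg$parclip_short_fraction
    hot <- stats::runif(n) < cfg$conversion_rate
    bg <- !hot & stats::runif(n) < cfg$background_conversion_rate
    conv_pos <- rep(NA_integer_, n)
    conv_pos[hot] <- trfs$hotspot[ti[hot]]
    for (r in which(bg)) {
      ts <- t_pos[[ti[r]]]
      if (length(ts)) conv_pos[r] <- sample1(ts)
    }
    sq <- trfs$sequence[ti]
    has_conv <- !is.na(conv_pos)
    substr(sq[has_conv], conv_pos[has_conv], conv_pos[has_conv]) <- "C"
    keep_len <- integer(n)
    keep_len[short] <- sample(12:15, sum(short), replace = TRUE)
    sq[short] <- substr(sq[short], 1L, keep_len[short])
    conv_pos[short & has_conv & conv_pos > keep_len] <- NA_integer_
    rows <- tibble::tibble(
      read_id = sprintf("pc%05d", seq_len(n)), sequence = sq,
      sample = samples, trf_id = trfs$trf_id[ti],
      gene_id = trfs$gene_id[ti], short = short,
      conversion_trf_pos = conv_pos,
      conversion_gene_pos = trfs$start[ti] + conv_pos - 1L)
    totals <- table(rows$sample[!rows$short])
    list(reads = rows[, c("read_id", "sequence", "sample")],
         sample_totals = stats::setNames(as.numeric(totals), names(totals)),
         truth = rows)
  })
}

#' Simulate an icSHAPE-style reactivity track over the transcriptome
#'
#' Background scores are i.i.d. uniform on \[0, 1\]; each planted target site
#' is double-stranded with probability `ds_probability`, in which case its
#' motif-region scores are shifted down by `reactivity_delta` (up for
#' single-stranded), clipped to \[0, 1\]. A `reactivity_na_rate` fraction of
#' positions is dropped to exercise missing-data handling.
#'
#' @param config A [simulation_config()].
#' @param references Matching [make_references()] output.
#' @return List with `track` (tibble `transcript_id`, `position`, `score`)
#'   and `site_truth` (tibble with the planted structure class per site).
#' @export
simulate_reactivity <- function(config, references) {
  cfg <- config
  tx <- references$transcripts
  sites <- references$sites
  withr::with_seed(cfg$seed + 3L, {
    track <- purrr::map_dfr(seq_len(nrow(tx)), function(j) {
      L <- nchar(tx$sequence[j])
      tibble::tibble(transcript_id = tx$transcript_id[j],
                     position = seq_len(L), score = stats::runif(L))
    })
    cls <- character(nrow(sites))
    if (nrow(sites)) {
      for (k in seq_len(nrow(sites))) {
        ds <- stats::runif(1) < cfg$ds_probability
        cls[k] <- if (ds) "DS" else "SS"
        sel <- track$transcript_id == sites$transcript_id[k] &
          track$position >= sites$site_start[k] &
          track$position <= sites$site_end[k]
        shift <- if (ds) -cfg$reactivity_delta else cfg$reactivity_delta
        track$score[sel] <- pmin(1, pmax(0, track$score[sel] + shift))
      }
    }
    keep <- stats::runif(nrow(track)) >= cfg$reactivity_na_rate
    list(track = track[keep, ],
         site_truth = dplyr::bind_cols(sites,
                                       tibble::tibble(planted_class = cls)))
  })
}

#' Write a complete synthetic workspace to disk
#'
#' Emits every input the pipeline consumes — gene annotation TSV + FASTA,
#' transcript annotation TSV + FASTA, chimeric reads FASTA, PAR-CLIP reads
#' FASTA + per-sample totals TSV, reactivity TSV — plus the ground-truth
#' tables.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and `files` (named
#'   paths).
#' @export
simulate_workspace <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- make_references(config)
  clash <- simulate_clash_reads(config, refs)
  parclip <- simulate_parclip_reads(config, refs)
  react <- simulate_reactivity(config, refs)
  f <- function(x) file.path(dir, x)
  files <- c(gene_annotation = f("genes.tsv"), gene_fasta = f("genes.fa"),
             tx_annotation = f("transcripts.tsv"), tx_fasta = f("transcripts.fa"),
             clash_reads = f("clash_reads.fa"),
             parclip_reads = f("parclip_reads.fa"),
             parclip_samples = f("parclip_samples.tsv"),
             reactivity = f("reactivity.tsv"),
             truth_trfs = f("truth_trfs.tsv"), truth_sites = f("truth_sites.tsv"),
             truth_clash = f("truth_clash.tsv"),
             truth_parclip = f("truth_parclip.tsv"),
             truth_reactivity = f("truth_reactivity.tsv"))
  write_gene_models(refs$genes, files["gene_annotation"], files["gene_fasta"])
  write_transcript_models(refs$transcripts, files["tx_annotation"], files["tx_fasta"])
  writeLines(paste0(">", clash$reads$read_id, "\n", clash$reads$sequence),
             files["clash_reads"])
  writeLines(paste0(">", parclip$reads$read_id, " ", parclip$reads$sample,
                    "\n", parclip$reads$sequence),
             files["parclip_reads"])
  readr::write_tsv(tibble::tibble(sample = names(parclip$sample_totals),
                                  total = parclip$sample_totals),
                   files["parclip_samples"])
  readr::write_tsv(react$track, files["reactivity"])
  readr::write_tsv(dplyr::select(refs$trfs, -"motif_matrix", -"gene_index"),
                   files["truth_trfs"])
  readr::write_tsv(refs$sites, files["truth_sites"])
  readr::write_tsv(clash$truth, files["truth_clash"])
  readr::write_tsv(parclip$truth, files["truth_parclip"])
  readr::write_tsv(react$site_truth, files["truth_reactivity"])
  invisible(list(references = refs, clash = clash, parclip = parclip,
                 reactivity = react, files = files))
}
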