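test_that("find_trf_arm returns the longest anchored exact match", {
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  g1 <- paste0(genes$sequence[1], "CCA")

  # forward: 18 nt copy of the CCA-extended 3' end + 22 nt non-tRNA tail
  arm18 <- substr(g1, 58, 75)
  read <- paste0(arm18, strrep("GAGTC", 5)[1], "AGAGTCAGAGTCAGAGTCAGA")
  read <- paste0(arm18, "GAGTCAGAGTCAGAGTCAGAGT")
  hit <- find_trf_arm(read, idx, "forward")
  expect_equal(c(hit$read_start, hit$read_end), c(1L, 18L))
  expect_equal(hit$genes$gene_id[1], "AlaAGC-001")

  # reverse: 20 nt tail + 18 nt gene suffix
  readr_ <- paste0("GAGTCAGAGTCAGAGTCAGA", arm18)
  hit2 <- find_trf_arm(readr_, idx, "reverse")
  expect_equal(c(hit2$read_start, hit2$read_end), c(21L, 38L))

  # no 16+ anchored match
  expect_null(find_trf_arm(strrep("GAGTC", 8), idx, "forward"))
  expect_error(find_trf_arm("", idx, "forward"), class = "trf_empty_read")
})

test_that("find_trf_arm agrees with an exhaustive anchored-substring scan", {
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  spaces <- c(paste0(genes$sequence, "CCA"),
              paste0(genes$sequence, genes$trailer))
  oracle <- function(read, orientation) {
    n <- nchar(read)
    best <- 0L
    for (k in seq(16L, n)) {
      sub <- if (orientation == "forward") substr(read, 1, k)
             else substr(read, n - k + 1, n)
      found <- FALSE
      for (g in spaces) {
        m <- nchar(g) - k + 1L
        if (m >= 1L) {
          for (p in seq_len(m)) {
            if (substr(g, p, p + k - 1L) == sub) { found <- TRUE; break }
          }
        }
        if (found) break
      }
      if (found) best <- k
    }
    best
  }
  withr::with_seed(7, {
    reads <- c(
      replicate(20, paste0(substr(spaces[1], s <- sample(1:55, 1), s + 17),
                           toy_random_seq(sample(10:25, 1)))),
      replicate(20, paste0(toy_random_seq(sample(10:25, 1)),
                           substr(spaces[2], s <- sample(1:55, 1), s + 19))),
      replicate(10, toy_random_seq(40))
    )
  })
  for (read in reads) {
    for (ori in c("forward", "reverse")) {
      hit <- find_trf_arm(read, idx, ori)
      got <- if (is.null(hit)) 0L else hit$read_end - hit$read_start + 1L
      expect_identical(got, oracle(read, ori))
    }
  }
})

test_that("split_read enumerates rejection reasons and partitions the read", {
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  target22 <- "GAGTCAGAGTCAGAGTCAGAGT"
  tx <- toy_transcripts(insert = target22)

  # read fully inside a tRNA gene -> trna_dominated (fraction 1.0 >= 0.8)
  res <- split_read("r1", substr(genes$sequence[1], 1, 40), idx, tx, "forward")
  expect_s3_class(res, "trf_rejection")
  expect_equal(unclass(res), "trna_dominated")

  # 36 nt arm in a 40 nt read: 0.9 >= 0.8 -> trna_dominated
  res <- split_read("r2", paste0(substr(genes$sequence[1], 1, 36), "GAGT"),
                    idx, tx, "forward")
  expect_equal(unclass(res), "trna_dominated")

  # 18 nt guide + 22 nt exact mRNA substring -> mRNA decomposition
  guide <- substr(paste0(genes$sequence[1], "CCA"), 58, 75)
  d <- split_read("r3", paste0(guide, target22), idx, tx, "forward")
  expect_s3_class(d, "tbl_df")
  expect_equal(d$category, "mRNA")
  expect_equal(d$trf_seq, guide)
  expect_equal(d$target_seq, target22)
  expect_lt((d$target_read_start - 1) / d$read_length, 0.8)
  # arms partition the read exactly
  expect_equal(d$target_read_start, nchar(guide) + 1L)
  expect_equal(d$target_read_end, nchar(guide) + nchar(target22))

  # short target
  res <- split_read("r4", paste0(guide, "GAGTCAGA"), idx, tx, "forward")
  expect_equal(unclass(res), "target_too_short")

  # unannotated target
  res <- split_read("r5", paste0(guide, "GAGTCAGAGTTTGACCAGTAG"), idx, tx,
                    "forward")
  expect_equal(unclass(res), "target_unannotated")

  # no anchored arm at all
  res <- split_read("r6", strrep("GAGTCAGA", 5), idx, tx, "forward")
  expect_equal(unclass(res), "no_trf_arm")
})

test_that("tRF-tRF chimeras are classified and excluded from the pair stream", {
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  a <- substr(genes$sequence[1], 1, 18)
  b <- substr(genes$sequence[2], 59, 76)
  expect_equal(detect_trf_trf(paste0(a, b), idx), "different_gene_pair")
  a2 <- substr(genes$sequence[1], 50, 70)
  expect_equal(detect_trf_trf(paste0(a, a2), idx), "same_gene_disjoint")
  target22 <- "GAGTCAGAGTCAGAGTCAGAGT"
  expect_equal(detect_trf_trf(paste0(a, target22), idx), "not_trf_trf")

  tx <- toy_transcripts(insert = target22)
  reads <- tibble::tibble(
    read_id = c("tt", "pair"),
    sequence = c(paste0(a, b),
                 paste0(substr(paste0(genes$sequence[1], "CCA"), 58, 75),
                        target22)))
  out <- split_reads(reads, idx, tx, "both")
  expect_equal(out$trf_trf$read_id, "tt")
  expect_equal(out$decompositions$read_id, "pair")
})

test_that("targets are annotated by majority region overlap with precedence", {
  # regions: 5UTR 1-50, CDS 51-200, 3UTR 201-300
  tx <- toy_transcripts()
  seg_3utr <- substr(tx$sequence[1], 210, 230)
  ann <- annotate_target(seg_3utr, tx)
  expect_equal(ann$category, "mRNA")
  expect_equal(ann$region, "3UTR")

  seg_rrna <- substr(tx$sequence[2], 50, 70)
  ann2 <- annotate_target(seg_rrna, tx)
  expect_equal(ann2$category, "rRNA")
  expect_true(is.na(ann2$region))

  # spans CDS/3UTR boundary: 12 nt in CDS, 8 in 3UTR -> CDS by majority
  seg_span <- substr(tx$sequence[1], 189, 208)
  ann3 <- annotate_target(seg_span, tx)
  expect_equal(ann3$region, "CDS")
  # 8 in CDS, 12 in 3UTR -> 3UTR
  seg_span2 <- substr(tx$sequence[1], 193, 212)
  expect_equal(annotate_target(seg_span2, tx)$region, "3UTR")

  expect_null(annotate_target("GAGTCAGAGTTTGACCAGTAG", tx))
})

test_that("pair tallies conserve read counts and flag two-read support", {
  d <- tibble::tibble(
    read_id = paste0("r", 1:4),
    trf_name = c("x", "x", "x", "y"), trf_type = c("3p", "3p", "3p", "5p"),
    transcript_id = "t1", category = "mRNA",
    tx_start = c(5L, 5L, 5L, 9L), tx_end = c(24L, 24L, 24L, 28L),
    orientation = "forward", target_seq = "ACGT")
  out <- tally_pairs(d)
  expect_equal(sort(out$pairs$read_support), c(1L, 3L))
  expect_equal(out$pairs$two_read_supported, out$pairs$read_support >= 2L)
  expect_equal(sum(out$summary$reads), nrow(d))
  expect_equal(sum(out$summary$reads_two_plus), 3L)
  empty <- tally_pairs(d[0, ])
  expect_equal(nrow(empty$pairs), 0L)
  expect_equal(nrow(empty$summary), 0L)
})

test_that("noise-free generator reads are fully and correctly decomposed", {
  cfg <- simulation_config(seed = 31, n_clash_reads = 250,
                           trf_trf_fraction = 0.04, pure_trna_fraction = 0.04)
  refs <- make_references(cfg)
  clash <- simulate_clash_reads(cfg, refs)
  idx <- build_gene_index(refs$genes)
  out <- split_reads(clash$reads, idx, refs$transcripts, "both")
  tp <- clash$truth[clash$truth$kind == "pair", ]
  m <- dplyr::inner_join(tp, out$decompositions, by = "read_id",
                         suffix = c("_truth", ""))
  expect_equal(nrow(m), nrow(tp))  # 100% decomposed
  expect_equal(m$trf_name, m$trf_name_truth)
  expect_equal(m$orientation, m$orientation_truth)
  expect_equal(m$transcript_id, m$transcript_id_truth)
  # tally marginals conserve accepted reads
  tal <- tally_pairs(out$decompositions)
  expect_equal(sum(tal$summary$reads), nrow(out$decompositions))
  # tRF-tRF truth recovered and excluded from the pair stream
  tt <- clash$truth[clash$truth$kind == "trf_trf", ]
  m2 <- dplyr::inner_join(tt, out$trf_trf, by = "read_id",
                          suffix = c("_truth", ""))
  expect_equal(nrow(m2), nrow(tt))
  expect_equal(m2$classification, m2$classification_truth)
})
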