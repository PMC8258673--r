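test_that("dinucleotide shuffle preserves dinucleotide counts", {
  count_di <- function(s) {
    x <- strsplit(s, "")[[1]]
    sort(table(paste0(x[-length(x)], x[-1])))
  }
  withr::with_seed(19, {
    for (s in replicate(30, toy_random_seq(sample(20:60, 1)))) {
      sh <- dinuc_shuffle(s)
      expect_equal(nchar(sh), nchar(s))
      expect_equal(count_di(sh), count_di(s))
    }
  })
})

test_that("target assembly filters polyT, collapses duplicates, keeps weights", {
  withr::with_seed(23, {
    clean <- strip_t_runs(random_targets(27, 30))
    polyt <- paste0(strip_t_runs(random_targets(3, 20)), "TTTTTT")
  })
  pairs <- tibble::tibble(target_seq = c(clean, polyt, clean[1]),
                          read_support = c(rep(1L, 30), 4L))
  out <- assemble_target_set(pairs)
  expect_equal(out$status, "ok")
  expect_equal(nrow(out$targets), 27L)
  expect_equal(out$n_removed_polyt, 3L)
  expect_equal(out$targets$weight[out$targets$sequence == clean[1]], 5)

  small <- assemble_target_set(tibble::tibble(target_seq = clean[1:5]))
  expect_equal(small$status, "insufficient_targets")
})

test_that("EM discovery recovers a planted motif and stays quiet on noise", {
  withr::with_seed(29, targets <- planted_targets(40, "GTCACGTA"))
  m <- discover_motif(targets, width_range = 8, seed = 4)
  expect_s3_class(m, "trf_pwm")
  expect_lt(m$e_value, 0.01)
  planted <- matrix(1 / 30, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  planted[cbind(match(strsplit("GTCACGTA", "")[[1]], rownames(planted)), 1:8)] <- 0.9
  cors <- vapply(1:8, function(j) stats::cor(m$matrix[, j], planted[, j]),
                 numeric(1))
  expect_gt(mean(cors), 0.9)

  withr::with_seed(30, noise <- random_targets(40))
  expect_null(discover_motif(noise, width_range = 8, seed = 4))
})

test_that("identical target sequences give a maximally informative motif", {
  targets <- rep(paste0("ACGTACGTGGCATGCATCAA"), 12)
  m <- discover_motif(targets, width_range = 8, seed = 1, force = TRUE)
  # information near the pseudocount-limited maximum, consensus in the target
  expect_gt(mean(pwm_information(m$matrix)), 1.5)
  consensus <- paste(rownames(m$matrix)[apply(m$matrix, 2, which.max)],
                     collapse = "")
  expect_true(grepl(consensus, targets[1], fixed = TRUE))
})

test_that("tidy/glance/matrix-file round trips describe the same motif", {
  withr::with_seed(33, targets <- planted_targets(30, "GTCACGTA"))
  m <- discover_motif(targets, width_range = 8, seed = 2)
  m <- match_back(m, paste0("GAGCA", "TACGTGAC", "TTGAC"), trf_name = "toy-N-i-6-13")
  td <- tidy(m)
  expect_equal(nrow(td), 4 * m$width)
  expect_equal(sum(td$probability), m$width)
  gl <- glance(m)
  expect_equal(gl$trf_name, "toy-N-i-6-13")
  path <- withr::local_tempfile(fileext = ".txt")
  write_motif_matrix(m, path)
  back <- read_motif_matrix(path)
  expect_equal(back$matrix, m$matrix, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$trf_interval, m$trf_interval)
})

test_that("exact PWM p-values equal enumeration and behave monotonely", {
  withr::with_seed(37, {
    m <- matrix(stats::rexp(20), 4, 5, dimnames = list(c("A","C","G","T"), NULL))
    m <- sweep(m, 2, colSums(m), "/")
  })
  lod <- log2(m) - log2(0.25)
  words <- as.matrix(expand.grid(rep(list(1:4), 5)))
  scores <- vapply(seq_len(nrow(words)), function(i)
    sum(lod[cbind(words[i, ], 1:5)]), numeric(1))
  for (s in stats::quantile(scores, c(0.05, 0.25, 0.5, 0.9, 1))) {
    expect_lt(abs(pwm_exact_pvalue(m, s) - mean(scores >= s)), 1e-9)
  }
  thr <- sort(sample(scores, 20))
  pv <- vapply(thr, function(s) pwm_exact_pvalue(m, s), numeric(1))
  expect_true(all(diff(pv) <= 0))

  single <- matrix(0, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  single[cbind(c(1, 2, 3, 4, 1), 1:5)] <- 1
  top <- sum(log2(1 / 0.25))
  expect_equal(pwm_exact_pvalue(single, top), 0.25^5)
})

test_that("match-back scans the reverse complement onto guide coordinates", {
  withr::with_seed(39, guide <- toy_random_seq(30))
  core <- substr(guide, 10, 17)
  site <- chartr("ACGT", "TGCA", paste(rev(strsplit(core, "")[[1]]), collapse = ""))
  pwm <- matrix(1 / 30, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(strsplit(site, "")[[1]], rownames(pwm)), 1:8)] <- 0.9
  hit <- pwm_match_pvalue(pwm, guide)
  expect_equal(hit$trf_interval, c(10L, 17L))
  expect_lt(hit$p_value, 0.001)
  expect_error(pwm_match_pvalue(pwm, "ACGTA"), class = "trf_bad_interval")

  # scrambled guides rarely carry a complementary site
  withr::with_seed(40, {
    ps <- replicate(50, {
      scr <- paste(sample(strsplit(guide, "")[[1]]), collapse = "")
      pwm_match_pvalue(pwm, scr)$p_value
    })
  })
  expect_gt(mean(ps > 0.001), 0.9)
})

test_that("motif comparisons use interval overlap and matrix correlation", {
  mk <- function(interval, mat = NULL, w = 8L) {
    if (is.null(mat)) {
      mat <- matrix(1 / 30, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
      mat[cbind(rep(1, w), 1:w)] <- 0.9
    }
    m <- trfclash:::new_trf_pwm(mat, ncol(mat), 1e-4, 0, 10, 10, 10)
    m$trf_interval <- interval
    m
  }
  a <- mk(c(2L, 10L), w = 9L)
  expect_equal(compare_motifs(a, a)$class, "identical")
  b <- mk(c(5L, 12L)); b2 <- mk(c(2L, 9L))
  cmp <- compare_motifs(b2, b)
  expect_equal(cmp$class, "overlap_ge4")
  expect_equal(cmp$overlap_nt, 5L)
  expect_equal(compare_motifs(mk(c(1L, 6L), w = 6L), mk(c(13L, 18L), w = 6L))$class,
               "disjoint")
  expect_equal(compare_motifs(mk(c(1L, 8L)), NULL)$class, "one_missing")
})

test_that("the upstream-downstream binomial test gives its reference values", {
  expect_equal(binomial_side_test(60, 85), 1.87e-4, tolerance = 0.005)
  expect_equal(binomial_side_test(53, 73), 1.42e-4, tolerance = 0.005)
  expect_equal(binomial_side_test(1, 2), 1.0)
  # two-sided symmetry at even odds
  for (n in c(10, 25, 85)) {
    k <- sample.int(n, 1)
    expect_equal(binomial_side_test(k, n), binomial_side_test(n - k, n))
  }
  cmp <- tibble::tibble(fwd_start = c(1, 2, 9, 4, 4), rev_start = c(5, 6, 2, 8, 4))
  out <- upstream_downstream_test(cmp)
  expect_equal(out$n_fwd_upstream, 3L)  # ties excluded
  expect_equal(out$n_rev_upstream, 1L)
  expect_equal(out$p_value, binomial_side_test(3, 4))
  expect_error(upstream_downstream_test(cmp[5, ]), class = "trf_empty_input")
})

test_that("ranking flags top terciles with shared ties", {
  tbl <- tibble::tibble(trf_name = paste0("t", 1:9),
                        n_targets = 9:1, read_support = 9:1,
                        e_value = seq(1e-9, 1e-2, length.out = 9),
                        matchback_pvalue = seq(1e-9, 1e-3, length.out = 9))
  rk <- rank_motifs(tbl)
  expect_equal(sum(rk$top_n_targets), 3L)
  expect_equal(sum(rk$high_confidence), 3L)
  # independent sort-based oracle
  oracle <- tbl$trf_name[order(-tbl$n_targets)][1:3]
  expect_setequal(rk$trf_name[rk$top_n_targets], oracle)

  even <- tbl
  even$n_targets <- 5; even$read_support <- 5
  even$e_value <- 1e-4; even$matchback_pvalue <- 1e-4
  rk2 <- rank_motifs(even)
  expect_true(all(rk2$high_confidence))
  expect_error(rank_motifs(tbl[1:2, ]))
})

test_that("pooling orientations rescues weak per-orientation evidence", {
  withr::with_seed(43, {
    fwd <- tibble::tibble(sequence = planted_targets(8, "GTCACGTA"), weight = 1)
    rev <- tibble::tibble(sequence = planted_targets(8, "GTCACGTA"), weight = 1)
  })
  th <- trf_thresholds()
  expect_equal(assemble_target_set(
    tibble::tibble(target_seq = fwd$sequence), th)$status,
    "insufficient_targets")
  pooled <- combine_orientations(fwd, rev, th, seed = 6, width_range = 8)
  expect_s3_class(pooled, "trf_pwm")
  expect_equal(pooled$orientation, "combined")
  expect_lt(pooled$e_value, 0.01)
  expect_error(combine_orientations(fwd[1:2, ], rev[1:3, ], th, seed = 6),
               class = "trf_insufficient_targets")
})

test_that("polyT decoys mask the planted motif unless filtered out", {
  withr::with_seed(47, {
    clean <- planted_targets(14, "GTCACGTA", len = 36)
    decoys <- vapply(random_targets(16, 20), function(s) {
      p <- sample(3:8, 1)
      paste0(substr(s, 1, p), strrep("T", sample(9:12, 1)),
             substr(s, p + 1, 20))
    }, character(1), USE.NAMES = FALSE)
  })
  pairs <- tibble::tibble(target_seq = c(clean, decoys))
  unfiltered <- discover_motif(pairs$target_seq, width_range = 8, seed = 8,
                               force = TRUE)
  expect_gt(mean(unfiltered$matrix["T", ]), 0.7)  # T-run decoys dominate

  filtered_set <- assemble_target_set(pairs)
  expect_equal(nrow(filtered_set$targets), 14L)
  m <- discover_motif(filtered_set$targets, width_range = 8, seed = 8)
  expect_lt(mean(m$matrix["T", ]), 0.5)
  planted <- matrix(1 / 30, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  planted[cbind(match(strsplit("GTCACGTA", "")[[1]], rownames(planted)), 1:8)] <- 0.9
  best <- -2  # aligned to within one column
  for (sh in -1:1) {
    cols <- which(seq_len(8) + sh >= 1 & seq_len(8) + sh <= 8)
    best <- max(best, mean(vapply(cols, function(j)
      stats::cor(m$matrix[, j + sh], planted[, j]), numeric(1))))
  }
  expect_gt(best, 0.8)
})
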