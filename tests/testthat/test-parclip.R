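test_that("alignment prefers perfect matches and admits only T->C", {
  genes <- toy_genes()
  g1 <- genes$sequence[1]
  perfect <- substr(g1, 5, 24)
  conv <- perfect
  tpos <- which(strsplit(perfect, "")[[1]] == "T")[2]
  substr(conv, tpos, tpos) <- "C"
  ag <- perfect
  apos <- which(strsplit(perfect, "")[[1]] == "A")[1]
  substr(ag, apos, apos) <- "G"
  two <- conv
  t2 <- which(strsplit(perfect, "")[[1]] == "T")[3]
  substr(two, t2, t2) <- "C"
  reads <- tibble::tibble(
    read_id = c("perfect", "tc", "ag", "two", "short"),
    sequence = c(perfect, conv, ag, two, substr(g1, 5, 18)))
  out <- align_parclip_reads(reads, genes)
  expect_equal(out$n_too_short, 1L)
  aln <- out$alignments
  expect_setequal(aln$read_id, c("perfect", "tc"))
  expect_equal(aln$mismatches[aln$read_id == "perfect"], 0L)
  expect_true(is.na(aln$conversion_pos[aln$read_id == "perfect"]))
  expect_equal(aln$conversion_pos[aln$read_id == "tc"], 4L + tpos)
  expect_equal(out$n_unaligned, 2L)
})

test_that("a perfect placement anywhere beats any one-mismatch placement", {
  base <- "ACGTTGCAGTCGATTGCAGC"   # reference 20-mer with a T at position 5
  read <- base
  substr(read, 5, 5) <- "C"        # read carries the conversion
  withr::with_seed(53, {
    geneA <- paste0(toy_random_seq(20), base, toy_random_seq(36))  # 1mm home
    geneB <- paste0(toy_random_seq(30), read, toy_random_seq(26))  # exact home
  })
  genes <- gene_models(c("A-001", "B-001"), "N", c(geneA, geneB), 33, 39)
  out <- align_parclip_reads(tibble::tibble(read_id = "r", sequence = read),
                             genes)
  # gene A sorts first and offers a T->C placement, but the perfect match in
  # gene B must win
  expect_equal(out$alignments$mismatches, 0L)
  expect_equal(out$alignments$gene_id, "B-001")
  # without gene B the same read aligns with the single T->C recorded
  out2 <- align_parclip_reads(tibble::tibble(read_id = "r", sequence = read),
                              genes[1, ])
  expect_equal(out2$alignments$mismatches, 1L)
  expect_equal(out2$alignments$conversion_pos, 25L)
})

test_that("conversion profiles are RPM normalised and conserve mass", {
  aln <- tibble::tibble(
    read_id = paste0("r", 1:5),
    sample = c("s1", "s1", "s2", "s2", "s2"),
    gene_id = "g", gene_start = 1L, gene_end = 20L,
    mismatches = c(1L, 1L, 1L, 0L, 1L),
    conversion_pos = c(10L, 10L, 10L, NA, 4L))
  totals <- c(s1 = 1e6, s2 = 2e6)
  prof <- conversion_profile(aln, totals)
  expect_equal(prof$profile$rpm[prof$profile$position == 10], 1 + 1 + 0.5)
  expect_equal(sum(prof$profile$rpm), 2 * 1 + 2 * 0.5)
  expect_equal(prof$top_sites$top_site, 10L)
  expect_false(prof$top_sites$tied)
  expect_error(conversion_profile(aln, c(s1 = 0, s2 = 2e6)),
               class = "trf_bad_threshold")
  # no conversions at all -> NA top site
  prof0 <- conversion_profile(aln[4, ], totals)
  expect_true(is.na(prof0$top_sites$top_site))
  # single conversion in a million-read sample -> exactly 1 RPM
  prof1 <- conversion_profile(aln[1, ], c(s1 = 1e6))
  expect_equal(prof1$profile$rpm, 1.0)
})

test_that("ties for the top site break 5'-most and are flagged", {
  aln <- tibble::tibble(read_id = c("a", "b"), sample = "s1", gene_id = "g",
                        gene_start = 1L, gene_end = 20L, mismatches = 1L,
                        conversion_pos = c(12L, 7L))
  prof <- conversion_profile(aln, c(s1 = 1e6))
  expect_equal(prof$top_sites$top_site, 7L)
  expect_true(prof$top_sites$tied)
})

test_that("cross-species mapping requires full-length exact matches", {
  genes <- toy_genes()
  sq <- substr(genes$sequence[1], 4, 25)
  mm <- sq
  substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(mm, 5, 5))[1]
  out <- map_cross_species(
    tibble::tibble(trf_id = c("m1", "m2"), sequence = c(sq, mm),
                   conversion_pos = c(8L, 8L)),
    genes)
  expect_equal(out$n_dropped, 1L)
  expect_equal(out$mapped$offset, 3L)
  expect_equal(out$mapped$ref_position, 11L)
  ident <- map_cross_species(
    tibble::tibble(trf_id = "m3", sequence = genes$sequence[2],
                   conversion_pos = 10L), genes)
  expect_equal(ident$mapped$ref_position, 10L)
})

test_that("bitscore histograms place column information at site offsets", {
  uniform <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  m1 <- trfclash:::new_trf_pwm(uniform, 6L, 1e-3, 0, 5, 5, 5,
                               trf_name = "t1", trf_interval = c(2L, 7L))
  tops <- tibble::tibble(trf_name = c("t1", "t2"), top_site = c(8L, 8L))
  h <- bitscore_histogram(list(m1), tops)
  expect_true(all(h$histogram$cumulative_bits == 0))

  conserved <- uniform
  conserved[, 1] <- c(1, 0, 0, 0)  # fully conserved column = 2 bits
  m2 <- trfclash:::new_trf_pwm(conserved, 6L, 1e-3, 0, 5, 5, 5,
                               trf_name = "t2", trf_interval = c(3L, 8L))
  h2 <- bitscore_histogram(list(m2), tops)
  expect_equal(h2$histogram$cumulative_bits[h2$histogram$offset == -5], 2)

  # guide without a top site is skipped and counted
  h3 <- bitscore_histogram(list(m1, m2),
                           tibble::tibble(trf_name = "t2", top_site = 8L))
  expect_equal(h3$n_skipped, 1L)
})

test_that("side bias test shares the exact binomial machinery", {
  per_trf <- tibble::tibble(trf_name = paste0("t", 1:10),
                            upstream_bits = 5, downstream_bits = 1)
  out <- side_bias_test(per_trf)
  expect_equal(out$n_upstream, 10L)
  expect_equal(out$p_value, 2 * 0.5^10)
  even <- tibble::tibble(trf_name = paste0("t", 1:10),
                         upstream_bits = rep(c(5, 1), 5),
                         downstream_bits = rep(c(1, 5), 5))
  expect_equal(side_bias_test(even)$p_value, 1.0)
  tied <- tibble::tibble(trf_name = "t", upstream_bits = 2, downstream_bits = 2)
  expect_error(side_bias_test(tied), class = "trf_empty_input")
})

test_that("planted hotspots are recovered from simulated PAR-CLIP reads", {
  cfg <- simulation_config(seed = 59, n_genes = 3L, trfs_per_gene = 1L,
                           sites_per_trf = 0L, n_parclip_reads = 2000L)
  refs <- make_references(cfg)
  pc <- simulate_parclip_reads(cfg, refs)
  out <- align_parclip_reads(pc$reads, refs$genes)
  expect_equal(out$n_too_short, sum(pc$truth$short))
  prof <- conversion_profile(out$alignments, pc$sample_totals)
  planted <- unique(tibble::tibble(
    gene_id = refs$trfs$gene_id,
    pos = refs$trfs$start + refs$trfs$hotspot - 1L))
  for (i in seq_len(nrow(prof$top_sites))) {
    g <- prof$top_sites$gene_id[i]
    expect_true(prof$top_sites$top_site[i] %in% planted$pos[planted$gene_id == g])
  }
})
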