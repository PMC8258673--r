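test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, n_clash_reads = 120,
                           n_parclip_reads = 200)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_workspace(cfg, d1)
  simulate_workspace(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("planted guides classify and name consistently across modules", {
  cfg <- simulation_config(seed = 6)
  refs <- make_references(cfg)
  for (i in seq_len(nrow(refs$trfs))) {
    g <- refs$genes[refs$genes$gene_id == refs$trfs$gene_id[i], ]
    expect_equal(classify_trf(refs$trfs$start[i], refs$trfs$end[i], g,
                              refs$trfs$space[i]),
                 refs$trfs$type[i])
  }
  parsed <- parse_trf_name(refs$trfs$trf_name)
  expect_equal(parsed$type, refs$trfs$type)
  expect_equal(parsed$start, refs$trfs$start)
})

test_that("an empty transcriptome is a valid configuration", {
  cfg <- simulation_config(seed = 8, sites_per_trf = 0L,
                           n_transcripts = c(mRNA = 0L, rRNA = 0L,
                                             miRNA = 0L, other_ncRNA = 0L))
  refs <- make_references(cfg)
  expect_equal(nrow(refs$transcripts), 0L)
  expect_equal(nrow(refs$sites), 0L)
})

test_that("reads respect the alphabet and length contracts of the parser", {
  cfg <- simulation_config(seed = 9, n_clash_reads = 300)
  refs <- make_references(cfg)
  clash <- simulate_clash_reads(cfg, refs)
  expect_false(any(grepl("[^ACGT]", clash$reads$sequence)))
  expect_true(all(nchar(clash$reads$sequence) >= 16))
  expect_equal(nrow(clash$truth), nrow(clash$reads))
})

test_that("full upstream binding with no ligation penalty skews forward", {
  cfg <- simulation_config(seed = 10, n_clash_reads = 2000,
                           upstream_prob = 1, cyclic_phosphate_penalty = 0,
                           polyt_site_rate = 0, trf_trf_fraction = 0,
                           pure_trna_fraction = 0)
  refs <- make_references(cfg)
  truth <- simulate_clash_reads(cfg, refs)$truth
  n_fwd <- sum(truth$orientation == "forward")
  expect_gt(n_fwd, nrow(truth) - n_fwd)
  expect_lt(binomial_side_test(n_fwd, nrow(truth)), 1e-6)
})

test_that("the cyclic-phosphate penalty depletes forward 5' halves tenfold", {
  # all guides bind upstream so the ligation penalty is the only difference
  # between the two types' forward odds
  cfg <- simulation_config(seed = 12, n_clash_reads = 6000,
                           cyclic_phosphate_penalty = 0.9, upstream_prob = 1,
                           trf_type_probs = c("3p" = 0.5, "5i" = 0.5),
                           polyt_site_rate = 0, trf_trf_fraction = 0,
                           pure_trna_fraction = 0,
                           n_genes = 8L, trfs_per_gene = 2L,
                           sites_per_trf = 8L,
                           n_transcripts = c(mRNA = 20L, rRNA = 0L,
                                             miRNA = 0L, other_ncRNA = 0L))
  refs <- make_references(cfg)
  truth <- simulate_clash_reads(cfg, refs)$truth
  odds <- function(type) {
    f <- sum(truth$trf_type == type & truth$orientation == "forward")
    r <- sum(truth$trf_type == type & truth$orientation == "reverse")
    f / r
  }
  ratio <- odds("5i") / odds("3p")
  expect_gt(ratio, 0.03)
  expect_lt(ratio, 0.3)
})

test_that("zero artifact rate leaves no polyT runs in targets", {
  cfg <- simulation_config(seed = 14, n_clash_reads = 500, polyt_site_rate = 0,
                           trf_trf_fraction = 0, pure_trna_fraction = 0)
  refs <- make_references(cfg)
  truth <- simulate_clash_reads(cfg, refs)$truth
  rep_tbl <- polyt_report(truth$target_seq)
  expect_equal(sum(rep_tbl$has_polyt_run), 0L)
})

test_that("PAR-CLIP simulation honours rates and the length filter", {
  cfg <- simulation_config(seed = 15, n_parclip_reads = 800,
                           conversion_rate = 0, background_conversion_rate = 0)
  refs <- make_references(cfg)
  pc <- simulate_parclip_reads(cfg, refs)
  expect_true(all(is.na(pc$truth$conversion_trf_pos)))

  cfg2 <- simulation_config(seed = 16, n_parclip_reads = 1000,
                            parclip_short_fraction = 0.2)
  refs2 <- make_references(cfg2)
  pc2 <- simulate_parclip_reads(cfg2, refs2)
  out <- align_parclip_reads(pc2$reads, refs2$genes)
  expect_equal(out$n_too_short, sum(nchar(pc2$reads$sequence) < 16))
  expect_equal(out$n_too_short, sum(pc2$truth$short))
  expect_equal(sum(pc2$sample_totals), sum(!pc2$truth$short))

  # a corrupted hotspot reference base is rejected
  refs_bad <- refs2
  i <- refs_bad$trfs$hotspot[1]
  substr(refs_bad$trfs$sequence[1], i, i) <- "G"
  expect_error(simulate_parclip_reads(cfg2, refs_bad),
               class = "trf_bad_config")
})

test_that("planted binding sides drive the side-bias test", {
  cfg <- simulation_config(seed = 18, n_genes = 100L, trfs_per_gene = 2L,
                           sites_per_trf = 0L, upstream_prob = 0.8,
                           n_transcripts = c(mRNA = 0L, rRNA = 0L,
                                             miRNA = 0L, other_ncRNA = 0L))
  refs <- make_references(cfg)
  pm <- planted_motif_objects(refs)
  h <- bitscore_histogram(pm$motifs, pm$top_sites)
  out <- side_bias_test(h)
  expect_gt(out$n_upstream, out$n_downstream)
  expect_lt(out$p_value, 1e-6)
  # histogram accumulates motif mass on both sides of the site
  expect_true(any(h$histogram$offset < 0) && any(h$histogram$offset > 0))
})
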