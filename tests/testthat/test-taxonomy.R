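toy_model <- function(L = 90, ls = 33, le = 39, trailer = "GATCCAGTACGGAT") {
  withr::with_seed(11, gene_models("GluCTC-002", "N", toy_random_seq(L),
                                   ls, le, trailer = trailer))
}

test_that("classification anchors fragments to gene landmarks", {
  g <- toy_model(L = 72)
  # 5' half ending in the anticodon loop
  expect_equal(classify_trf(1, 33, g[1, ]), "5i")
  expect_equal(trf_name("GluCTC-002", "N", "5i", 1, 33), "GluCTC-002-N-5i-1-33")
  # 5' fragment ending before the loop
  expect_equal(classify_trf(2, 20, g[1, ]), "5p")
  # 3' fragment ending at the appended CCA
  expect_equal(classify_trf(58, 75, g[1, ], space = "cca"), "3p")
  # fragment from the loop to the CCA end
  expect_equal(classify_trf(35, 75, g[1, ], space = "cca"), "3i")
  # internal fragment fits no anchored rule (loop [33,39])
  expect_equal(classify_trf(20, 28, g[1, ]), "i")
  # fragment ending 5 nt into the trailer
  expect_equal(classify_trf(60, 77, g[1, ], space = "trailer"), "3t")
  # trailer-only fragments (tRF-1) fold into 3t
  expect_equal(classify_trf(73, 86, g[1, ], space = "trailer"), "3t")
  expect_error(classify_trf(70, 80, g[1, ], space = "body"),
               class = "trf_bad_interval")
})

test_that("classification matches a direct rule transcription on a full grid", {
  g <- toy_model(L = 90)
  L <- 90L; ls <- 33L; le <- 39L; tl <- nchar(g$trailer[1])
  oracle <- function(start, end, space) {
    if (space == "trailer" && end >= L + 3L) return("3t")
    if (start <= 5L && end < ls) return("5p")
    if (start <= 5L && end >= ls && end <= le) return("5i")
    if (end >= L - 1L && start > le) return("3p")
    if (end >= L - 1L && start >= ls && start <= le) return("3i")
    "i"
  }
  for (space in c("cca", "trailer")) {
    max_end <- if (space == "cca") L + 3L else L + tl
    grid <- expand.grid(start = 1:max_end, end = 1:max_end)
    grid <- grid[grid$start <= grid$end, ]
    got <- mapply(function(s, e) classify_trf(s, e, g[1, ], space = space),
                  grid$start, grid$end)
    want <- mapply(oracle, grid$start, grid$end, MoreArgs = list(space = space))
    expect_identical(got, want)
  }
})

test_that("canonical names parse back to their fields", {
  p <- parse_trf_name("IleTAT-005-N-3t-70-90")
  expect_equal(p$gene_id, "IleTAT-005")
  expect_equal(p$type, "3t")
  expect_equal(parse_trf_name("Gene-1-NM-5p-2-20")$origin, "NM")
  withr::with_seed(5, {
    tbl <- tibble::tibble(
      gene_id = sprintf("Ala%s-%03d", sample(c("AGC", "CGC"), 1000, TRUE),
                        sample(1:999, 1000, TRUE)),
      origin = sample(c("N", "M", "NM"), 1000, TRUE),
      type = sample(c("5p", "5i", "3p", "3i", "3t", "i"), 1000, TRUE),
      start = sample(1:60, 1000, TRUE))
    tbl$end <- tbl$start + sample(15:30, 1000, TRUE)
  })
  names_out <- trf_name(tbl$gene_id, tbl$origin, tbl$type, tbl$start, tbl$end)
  expect_equal(parse_trf_name(names_out), tbl)
  expect_error(parse_trf_name("not-a-name"), class = "trf_bad_name")
})

test_that("length distributions conserve counts", {
  recs <- tibble::tibble(trf_type = c("3p", "3p", "5i"),
                         trf_start = c(55L, 55L, 1L), trf_end = c(72L, 72L, 33L),
                         orientation = c("forward", "forward", "reverse"))
  h <- length_distribution(recs)
  expect_equal(sum(h$count), 3)
  expect_equal(h$length[h$type == "3p"], 18L)
  expect_equal(nrow(length_distribution(recs[0, ])), 0L)
  one <- length_distribution(tibble::tibble(trf_type = "5i", length = 33L))
  expect_equal(nrow(one), 1L)
})

test_that("generator length modes surface in the distribution", {
  cfg <- simulation_config(seed = 17, n_genes = 60L, trfs_per_gene = 1L,
                           sites_per_trf = 0L,
                           trf_type_probs = c("3p" = 0.7, "5i" = 0.3))
  refs <- make_references(cfg)
  trfs <- refs$trfs
  h <- length_distribution(
    tibble::tibble(trf_type = trfs$type, length = trfs$length))
  h3p <- h[h$type == "3p", ]
  expect_equal(h3p$length[which.max(h3p$count)], 18L)
  expect_true(all(h$length[h$type == "5i"] >= 33 & h$length[h$type == "5i"] <= 36))
})

test_that("orientation comparison reproduces hand arithmetic", {
  same <- tibble::tibble(name = c("A", "B"), count = c(90, 10))
  cmp <- compare_orientations(same, same)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$table$fold_change, c(1, 1))

  swapped <- compare_orientations(
    tibble::tibble(name = c("A", "B"), count = c(90, 10)),
    tibble::tibble(name = c("A", "B"), count = c(10, 90)))
  expect_equal(sort(swapped$table$fold_change), c(1 / 9, 9))

  expect_error(compare_orientations(same[0, ], same[0, ]),
               class = "trf_empty_input")
})

test_that("pearson r matches the textbook formula and its invariances", {
  withr::with_seed(9, {
    f <- tibble::tibble(name = paste0("t", 1:30), count = rpois(30, 50) + 1)
    r <- tibble::tibble(name = paste0("t", 1:30), count = rpois(30, 50) + 1)
  })
  cmp <- compare_orientations(f, r)
  x <- f$count / sum(f$count); y <- r$count / sum(r$count)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp$pearson_r, hand, tolerance = 1e-12)
  # symmetric under swapping orientations
  expect_equal(compare_orientations(r, f)$pearson_r, cmp$pearson_r)
  # invariant to scaling all counts
  f2 <- f; f2$count <- f2$count * 17
  expect_equal(compare_orientations(f2, r)$pearson_r, cmp$pearson_r)
})

test_that("isodecoder level pools gene copies of one anticodon family", {
  f <- tibble::tibble(name = c("CysGCA-001-N-3p-58-75", "CysGCA-002-N-3p-58-75",
                               "GluCTC-001-N-5i-1-33"),
                      count = c(30, 20, 50))
  r <- tibble::tibble(name = c("CysGCA-001-N-3p-58-75", "GluCTC-001-N-5i-1-33"),
                      count = c(25, 75))
  cmp <- compare_orientations(f, r, level = "isodecoder")
  expect_equal(sort(cmp$table$item), c("CysGCA", "GluCTC"))
  expect_equal(cmp$table$freq_fwd[cmp$table$item == "CysGCA"], 0.5)
})
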