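# deterministic toy references used across the chimera / taxonomy tests

toy_bases <- c("A", "C", "G", "T")

toy_random_seq <- function(n) paste(sample(toy_bases, n, replace = TRUE),
                                    collapse = "")

# two intron-less genes with known sequences, loop [33, 39], short trailers
toy_genes <- function() {
  withr::with_seed(101, {
    gene_models(
      gene_id = c("AlaAGC-001", "GlyGCC-002"),
      origin = c("N", "N"),
      sequence = c(toy_random_seq(72), toy_random_seq(76)),
      loop_start = 33, loop_end = 39,
      trailer = c("ACGATCGGAT", "GATCCAGTAC"),
      cca_added = TRUE
    )
  })
}

# one mRNA with 5UTR/CDS/3UTR regions, one rRNA; mRNA carries a planted
# 22 nt target block at positions 101..122
toy_transcripts <- function(insert = NULL) {
  withr::with_seed(202, {
    mrna <- toy_random_seq(300)
    if (!is.null(insert)) substr(mrna, 101, 100 + nchar(insert)) <- insert
    transcript_models(
      transcript_id = c("mrna1", "rrna1"),
      category = c("mRNA", "rRNA"),
      sequence = c(mrna, toy_random_seq(200)),
      regions = list(
        tibble::tibble(region = c("5UTR", "CDS", "3UTR"),
                       start = c(1L, 51L, 201L), end = c(50L, 200L, 300L)),
        tibble::tibble(region = character(0), start = integer(0),
                       end = integer(0))
      )
    )
  })
}

# break chance T runs of 5+ so fixtures are polyT-free unless intended
strip_t_runs <- function(x) gsub("TTTTT", "TTCTT", x)

# random targets of length `len`, each carrying a planted `site` copied at
# per-position identity `identity`; free of chance polyT runs
planted_targets <- function(n, site, len = 40, identity = 0.9) {
  w <- nchar(site)
  replicate(n, {
    s <- sample(toy_bases, len, replace = TRUE)
    sv <- strsplit(site, "")[[1]]
    flip <- stats::runif(w) > identity
    sv[flip] <- vapply(sv[flip], function(b) sample(setdiff(toy_bases, b), 1),
                       character(1))
    p <- sample.int(len - w + 1L, 1L)
    s[p:(p + w - 1L)] <- sv
    strip_t_runs(paste(s, collapse = ""))
  })
}

random_targets <- function(n, len = 40) {
  replicate(n, paste(sample(toy_bases, len, replace = TRUE), collapse = ""))
}
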