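#' Analysis thresholds
#'
#' Single container for every tunable cutoff used across the pipeline, so
#' that each stage reads its constants from one place. Defaults are the
#' standard constants of this analysis: chimeric reads with >= 80% of their length
#' inside a tRNA are discarded, guide arms and PAR-CLIP reads shorter than
#' 16 nt are excluded, targets carrying runs of >= 5 consecutive Ts are
#' treated as library artifacts (with the last 10 nt of the target arm the
#' diagnostic window), motifs are kept at E-value < 0.01 and must match back
#' onto the guide at p < 0.001, and icSHAPE reactivity >= 0.5 calls a site
#' single-stranded.
#'
#' @param trna_fraction_max Maximum tolerated fraction of a chimeric read
#'   covered by the tRNA arm (reads at or above this are rejected).
#' @param min_trf_arm Minimum guide (tRF) arm length in nt.
#' @param min_target_arm Minimum target arm length in nt.
#' @param polyt_min_run Minimum run of consecutive Ts flagging a polyT
#'   artifact.
#' @param polyt_tail_window Length of the 3' window of the target arm
#'   inspected for tail polyT runs.
#' @param motif_evalue_max Motif significance threshold (E-value).
#' @param matchback_pvalue_max Guide match-back significance threshold.
#' @param reactivity_ss_cutoff Mean reactivity at or above which a motif
#'   region is called single-stranded.
#' @param random_kmer_width Width of the random k-mers drawn for the
#'   reactivity null.
#' @param min_parclip_read Minimum PAR-CLIP read length in nt.
#' @param min_motif_targets Minimum number of unique target sequences
#'   required before motif discovery is attempted.
#'
#' @return A list of class `trf_thresholds`.
#' @export
#' @examples
#' th <- trf_thresholds()
#' th$trna_fraction_max
trf_thresholds <- function(trna_fraction_max = 0.80,
                           min_trf_arm = 16L,
                           min_target_arm = 10L,
                           polyt_min_run = 5L,
                           polyt_tail_window = 10L,
                           motif_evalue_max = 0.01,
                           matchback_pvalue_max = 0.001,
                           reactivity_ss_cutoff = 0.5,
                           random_kmer_width = 12L,
                           min_parclip_read = 16L,
                           min_motif_targets = 10L) {
  th <- list(
    trna_fraction_max = trna_fraction_max,
    min_trf_arm = as.integer(min_trf_arm),
    min_target_arm = as.integer(min_target_arm),
    polyt_min_run = as.integer(polyt_min_run),
    polyt_tail_window = as.integer(polyt_tail_window),
    motif_evalue_max = motif_evalue_max,
    matchback_pvalue_max = matchback_pvalue_max,
    reactivity_ss_cutoff = reactivity_ss_cutoff,
    random_kmer_width = as.integer(random_kmer_width),
    min_parclip_read = as.integer(min_parclip_read),
    min_motif_targets = as.integer(min_motif_targets)
  )
  nums <- vapply(th, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                 logical(1))
  if (!all(nums)) {
    rlang::abort("all thresholds must be positive scalars",
                 class = "trf_bad_threshold")
  }
  if (th$trna_fraction_max >= 1) {
    rlang::abort("trna_fraction_max must lie in (0, 1)",
                 class = "trf_bad_threshold")
  }
  structure(th, class = c("trf_thresholds", "list"))
}

#' @export
print.trf_thresholds <- function(x, ...) {
  cat("<trf_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
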