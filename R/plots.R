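#' Plot tRF length distributions by type
#'
#' @param distribution Output of [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(distribution) {
  p <- ggplot2::ggplot(distribution,
                       ggplot2::aes(x = .data$length, y = .data$count,
                                    fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tRF length (nt)", y = "reads", fill = "tRF type") +
    ggplot2::theme_minimal()
  if ("orientation" %in% names(distribution)) {
    p <- p + ggplot2::facet_wrap(~orientation)
  }
  p
}

#' Scatter plot of dinucleotide-composition principal components
#'
#' @param pca A `trf_pca` object.
#' @param colour Optional vector (orientation, polyT flag, ...) aligned with
#'   the score rows.
#' @return A ggplot object.
#' @export
plot_pca_composition <- function(pca, colour = NULL) {
  d <- pca$scores
  if (!is.null(colour)) d$colour <- colour
  ev <- pca$explained_variance
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point(alpha = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), alpha = 0.6) +
    ggplot2::labs(colour = NULL)
}

#' Information-content logo profile of a fitted motif
#'
#' Stacked per-position base probabilities scaled by column information
#' content (a bar-style sequence logo).
#'
#' @param object A `trf_pwm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trf_pwm
#' @export
autoplot.trf_pwm <- function(object, ...) {
  d <- tidy.trf_pwm(object)
  d$height <- d$probability * d$bits
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$height,
                                  fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "motif position", y = "information (bits)",
                  title = if (!is.na(object$trf_name)) object$trf_name else NULL) +
    ggplot2::theme_minimal()
}

#' Plot the class-separated reactivity profile aligned at motif starts
#'
#' @param profile Output of [aligned_profile()].
#' @return A ggplot object.
#' @export
plot_aligned_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$mean_score,
                                        colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "position relative to motif start",
                  y = "mean reactivity", colour = "structure") +
    ggplot2::theme_minimal()
}

#' Plot cumulative motif bitscores around the conversion site
#'
#' @param x A `trf_bitscore_histogram`.
#' @return A ggplot object.
#' @export
plot_bitscore_histogram <- function(x) {
  ggplot2::ggplot(x$histogram, ggplot2::aes(x = .data$offset,
                                            y = .data$cumulative_bits)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "offset from top T→C conversion site (nt)",
                  y = "cumulative bitscore (bits)") +
    ggplot2::theme_minimal()
}
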