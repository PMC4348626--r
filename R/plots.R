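# ggplot2 autoplot methods for the main result types.

#' Plot a sequencing saturation curve
#'
#' @param object A [saturation_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sampled_copies, .data$genes_detected)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "sampled clean-tag copies", y = "distinct genes detected",
      title = "Sequencing saturation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a clean-tag copy-number distribution
#'
#' @param object A [copy_number_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot copy_number_dist
#' @export
autoplot.copy_number_dist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin, .data$n_tags)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "copies per distinct tag", y = "distinct tag types",
      title = "Clean-tag copy-number distribution"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-group pattern distributions
#'
#' @param object A [pattern_summary()] result.
#' @param ... Unused.
#' @return A ggplot (stacked proportions per group).
#' @method autoplot pattern_summary
#' @export
autoplot.pattern_summary <- function(object, ...) {
  dat <- object %>%
    mutate(pattern = factor(.data$pattern, levels = PATTERN_LEVELS))
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$prop, fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "proportion of classified genes", fill = "pattern",
      title = "Gene-action pattern distribution"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of pattern-trait correlations
#'
#' @param object A [correlate_patterns_traits()] result.
#' @param ... Unused.
#' @return A ggplot tile map with significance marks.
#' @method autoplot pattern_trait_cor
#' @export
autoplot.pattern_trait_cor <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$pattern, .data$trait, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$signif), size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC", high = "#B2182B") +
    ggplot2::labs(
      x = "expression pattern", y = NULL, fill = "Pearson r",
      title = "Pattern proportions vs trait heterosis"
    ) +
    ggplot2::theme_minimal()
}
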