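# ggplot2 helpers for the main result types.

#' Stacked composition barplot of a feature table
#'
#' @param table long count tibble (feature_id, sample_id, count).
#' @param top_n features beyond the `top_n` most abundant are lumped into
#'   "Other" for display.
#' @return a ggplot object.
#' @export
plot_composition <- function(table, top_n = 12) {
  ra <- add_relabund(table)
  keep <- ra %>%
    group_by(.data$feature_id) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total)) %>%
    head(top_n) %>%
    pull("feature_id")
  ra %>%
    mutate(feature = if_else(.data$feature_id %in% keep,
                             .data$feature_id, "Other")) %>%
    group_by(.data$sample_id, .data$feature) %>%
    summarise(rel_abund = sum(.data$rel_abund), .groups = "drop") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$rel_abund,
                                 fill = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Prevalence dot plot per group
#'
#' @param prev output of [prevalence()].
#' @param group_col grouping column to place on the x axis (default
#'   `site`).
#' @return a ggplot object.
#' @export
plot_prevalence <- function(prev, group_col = "site") {
  ggplot2::ggplot(prev,
                  ggplot2::aes(x = .data[[group_col]],
                               y = .data$prevalence,
                               size = .data$n)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~taxon) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Prevalence (infected fraction)",
                  size = "n") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.symbio_dbrda <- function(object, ...) {
  df <- object$anova
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$pseudo_f)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p = %.3f", .data$p)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "pseudo-F",
                  title = sprintf("Constrained variance: %.1f%%",
                                  100 * object$variance_explained)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
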