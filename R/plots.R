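#' Scatter plot of an overlap's paired methylation differences
#'
#' Mirrors the classic cross-contrast scatter: each overlapping feature
#' plotted by its methylation difference in contrast A (x) versus
#' contrast B (y), coloured by direction quadrant.
#'
#' @param object A [contrast_overlap] with a non-empty `pairs` element.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contrast_overlap
#' @export
autoplot.contrast_overlap <- function(object, ...) {
  if (is.null(object$pairs) || nrow(object$pairs) == 0L) {
    rlang::abort("autoplot.contrast_overlap: no overlapping pairs to plot")
  }
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$diff_a, y = .data$diff_b,
                               colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = sprintf("methylation difference, %s (pp)", object$labels[1]),
      y = sprintf("methylation difference, %s (pp)", object$labels[2]),
      colour = "direction") +
    ggplot2::theme_minimal()
}

#' Bar plot of genomic-context distribution profiles
#'
#' @param profile Result of [distribution_profile()].
#' @param category_type `"subregion"` or `"island_context"`.
#' @return A ggplot object.
#' @export
plot_distribution_profile <- function(profile,
                                      category_type = c("subregion",
                                                        "island_context")) {
  category_type <- match.arg(category_type)
  d <- dplyr::filter(profile$counts, .data$category_type == !!category_type)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(x = NULL, y = "regions", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Dot plot of per-subject DMR methylation levels by group
#'
#' @param means Long tibble from [dmr_subject_means()].
#' @param sheet Sample sheet (`sample_id`, `group`).
#' @param dmr_ids Regions to show (default: all in `means`).
#' @return A ggplot object.
#' @export
plot_dmr_levels <- function(means, sheet, dmr_ids = NULL) {
  d <- dplyr::inner_join(means, sheet[, c("sample_id", "group")],
                         by = "sample_id")
  if (!is.null(dmr_ids)) d <- dplyr::filter(d, .data$dmr_id %in% dmr_ids)
  d$group <- factor(d$group, c("control", "obesity", "crc"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean_beta,
                                  colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.3) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~dmr_id) +
    ggplot2::labs(x = NULL, y = "mean methylation level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of row-centered log-CPM values
#'
#' @param logcpm Log-CPM tibble from [log_cpm()].
#' @param gene_ids Genes to show (default: all).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(logcpm, gene_ids = NULL) {
  if (!is.null(gene_ids)) {
    logcpm <- dplyr::filter(logcpm, .data$gene_id %in% gene_ids)
  }
  long <- logcpm |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "logcpm") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(centered = .data$logcpm - mean(.data$logcpm)) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$centered)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row-centered\nlog-CPM") +
    ggplot2::theme_minimal()
}
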