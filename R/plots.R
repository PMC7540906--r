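#' Stacked-bar phylum composition per sample
#'
#' @param phylum_composition Tibble from [aggregate_phylum()].
#' @return A ggplot: per-sample stacked bars, faceted by region.
#' @export
plot_phylum_composition <- function(phylum_composition) {
  ggplot2::ggplot(phylum_composition,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$phylum)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::facet_wrap(~region, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = "phylum") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

#' Order composition of the retained isolates
#'
#' @param order_summary Tibble from [summarize_orders()].
#' @return A ggplot bar chart of isolate counts per order, labeled with
#'   percentages.
#' @export
plot_order_composition <- function(order_summary) {
  ggplot2::ggplot(order_summary,
                  ggplot2::aes(x = stats::reorder(.data$order,
                                                  -.data$n_isolates),
                               y = .data$n_isolates)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "isolates") +
    ggplot2::theme_minimal()
}

#' Heat-style matrix of order-cluster counts across region sets
#'
#' @param cluster_report Result of [compare_concatenations()] (or its
#'   `long` tibble).
#' @return A ggplot tile plot: orders x region sets, filled and labeled by
#'   cluster count — lower is better (1 = monophyletic).
#' @export
plot_cluster_counts <- function(cluster_report) {
  long <- if (is.data.frame(cluster_report)) cluster_report
          else cluster_report$long
  long$region_set <- factor(long$region_set,
                            levels = unique(long$region_set))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region_set, y = .data$order,
                                     fill = .data$n_clusters)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_clusters), size = 3) +
    ggplot2::scale_fill_gradient(low = "#2c7fb8", high = "#f03b20") +
    ggplot2::labs(x = "region set", y = NULL, fill = "clusters") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Default plot for a pipeline result
#'
#' @param object A `nema_pipeline` object.
#' @param ... Unused.
#' @return The order-cluster-count tile plot, or the order composition if
#'   no trees were built.
#' @method autoplot nema_pipeline
#' @export
autoplot.nema_pipeline <- function(object, ...) {
  if (!is.null(object$cluster_report)) {
    plot_cluster_counts(object$cluster_report)
  } else {
    plot_order_composition(object$order_summary)
  }
}
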