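## --- ggplot2 visualisations ---

#' Ranked miRNA expression plot
#'
#' Mean relative expression (global-mean units) from the most to the least
#' expressed miRNA, the ranked view of the normalized EV profile.
#'
#' @param ranking A [rank_mirnas()] table.
#' @param top Optionally restrict to the `top` highest-ranked miRNAs.
#' @return A ggplot object.
#' @export
plot_expression_rank <- function(ranking, top = NULL) {
  if (!is.null(top)) ranking <- dplyr::slice_head(ranking, n = top)
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$rank, y = .data$mean_rel_expr)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "rank (most to least expressed)",
                  y = "mean relative expression (global-mean units)") +
    ggplot2::theme_minimal()
}

#' Box plot of target degrees by DE direction
#'
#' The up- versus downregulated degree comparison underlying the enrichment
#' t-test.
#'
#' @param object An [enrichment_stats()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$direction, y = .data$degree,
                               fill = .data$direction)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#2980b9")) +
    ggplot2::labs(x = "DE direction",
                  y = "miRNA-target interactions per transcript (degree)") +
    ggplot2::theme_minimal()
}

#' Violin plot of a randomized-network null distribution
#'
#' Null values per node as violins with the observed value overlaid, the
#' standard display for randomized-network significance.
#'
#' @param object A [null_distribution()] result.
#' @param nodes Nodes to show (default: the 8 with the largest observed
#'   values).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_summary <- function(object, nodes = NULL, ...) {
  if (is.null(nodes))
    nodes <- names(sort(object$observed, decreasing = TRUE))[
      seq_len(min(8, length(object$observed)))]
  long <- dplyr::filter(tidy(object), .data$node %in% nodes)
  obs <- tibble(node = nodes, value = unname(object$observed[nodes]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", colour = "grey40") +
    ggplot2::geom_point(data = obs, colour = "#c0392b", size = 2) +
    ggplot2::labs(x = NULL,
                  y = paste0(object$measure, " (violin: ", object$n_random,
                             " rewired networks; point: observed)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Centrality landscape of a PPI network
#'
#' Betweenness against bridging centrality, coloured by centroid value, with
#' the network means drawn as reference lines; consensus hubs are the points
#' beyond both lines with above-mean centroid.
#'
#' @param object A [centrality_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_report <- function(object, ...) {
  means <- attr(object, "means", exact = TRUE)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$betweenness, y = .data$bridging,
                               colour = .data$centroid)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = means[["betweenness"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = means[["bridging"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "betweenness", y = "bridging centrality",
                  colour = "centroid") +
    ggplot2::theme_minimal()
}
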