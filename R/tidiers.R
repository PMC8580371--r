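## --- broom-style tidiers ---

#' Tidy an enrichment result
#'
#' One row per DE transcript with its direction and degree (number of
#' distinct miRNAs targeting it).
#'
#' @param x An [enrichment_stats()] result.
#' @param ... Unused.
#' @return A tibble with columns `transcript`, `direction`, `degree`.
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(x$target_degrees)
}

#' One-row summary of an enrichment result
#' @param x An [enrichment_stats()] result.
#' @param ... Unused.
#' @return A one-row tibble with the group means, their ratio, t-test
#'   results, coverage, and the mean up-target fraction.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(mean_degree_up = x$mean_degree_up,
         mean_degree_down = x$mean_degree_down,
         ratio = x$ratio,
         statistic = x$t$statistic,
         df = x$t$df,
         p_value = x$t$p_value,
         coverage_n = x$coverage_n,
         coverage_total = x$coverage_total,
         coverage_fraction = x$coverage_fraction,
         mean_up_target_fraction = x$mean_up_fraction,
         n_qualifying_mirnas = x$n_qualifying_mirnas,
         undefined = x$degenerate)
}

#' Tidy a null-distribution summary
#'
#' Long table of per-replicate null values, one row per (replicate, node),
#' the layout used for violin plots.
#'
#' @param x A [null_distribution()] result.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `node`, `measure`, `value`.
#' @export
tidy.null_summary <- function(x, ...) {
  nodes <- colnames(x$nulls)
  tibble(replicate = rep(seq_len(nrow(x$nulls)), times = length(nodes)),
         node = rep(nodes, each = nrow(x$nulls)),
         measure = x$measure,
         value = as.vector(x$nulls))
}

#' One-row summary of a null-distribution run
#' @param x A [null_distribution()] result.
#' @param ... Unused.
#' @return A one-row tibble with the measure, randomization scheme, counts
#'   and the smallest upper-tail empirical p-value.
#' @export
glance.null_summary <- function(x, ...) {
  tibble(measure = x$measure, scheme = x$scheme, n_random = x$n_random,
         n_swaps = x$n_swaps, n_nodes = length(x$observed),
         min_p_upper = min(x$p_upper))
}

#' Network-mean centralities of a centrality report
#' @param x A [centrality_report()].
#' @param ... Unused.
#' @return A one-row tibble of network-wide mean degree, betweenness,
#'   bridging and centroid values (the hub-selection reference).
#' @export
glance.centrality_report <- function(x, ...) {
  as_tibble(as.list(attr(x, "means", exact = TRUE)))
}

#' One-row summary of a hub set
#' @param x A [select_hubs()] result.
#' @param ... Unused.
#' @return A one-row tibble with the number of hubs, the selection mode and
#'   the required centralities.
#' @export
glance.hub_set <- function(x, ...) {
  tibble(n_hubs = nrow(x),
         mode = attr(x, "mode", exact = TRUE),
         required = paste(attr(x, "required", exact = TRUE),
                          collapse = "+"))
}
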