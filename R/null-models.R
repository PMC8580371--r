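## --- degree-preserving randomization and empirical significance ---

#' Degree-preserving network randomization
#'
#' Randomizes a network by repeated double-edge swaps: two edges (a,b), (c,d)
#' are replaced by (a,d), (c,b), accepting a swap only when it creates no
#' self-loop or duplicate edge (and, for bipartite networks, keeps every edge
#' across the partition). The degree sequence — and for bipartite networks
#' each side's degrees — is preserved exactly. Failed attempts count toward
#' `n_swaps` (attempt semantics), so runtime is predictable; accepted and
#' attempted counts are attached as attributes `swaps_accepted` /
#' `swaps_attempted`.
#'
#' @param net A [ppi_network()] or [build_bipartite()] network.
#' @param n_swaps Number of swap attempts (default `10 * n_edges`).
#' @param seed Optional integer seed; the (network, n_swaps, seed) triple
#'   determines the result.
#' @return A network of the same class with the same degree sequence.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "b", "c", "d"),
#'                                   protein_b = c("b", "c", "d", "a")))
#' rewire_degree_preserving(net, seed = 1)
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = NULL) {
  UseMethod("rewire_degree_preserving")
}

#' @export
rewire_degree_preserving.ppi_net <- function(net, n_swaps = NULL, seed = NULL) {
  m <- nrow(net$edges)
  if (m < 2) {
    warn("network has fewer than 2 edges; returned unchanged.")
    return(net)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  nodes <- net$nodes
  ei <- match(net$edges$from, nodes)
  ej <- match(net$edges$to, nodes)
  run <- function() {
    n <- length(nodes)
    adj <- matrix(FALSE, n, n)
    adj[cbind(ei, ej)] <- TRUE
    adj[cbind(ej, ei)] <- TRUE
    accepted <- 0L
    for (it in seq_len(n_swaps)) {
      e <- sample.int(m, 2)
      a <- ei[e[1]]; b <- ej[e[1]]
      c_ <- ei[e[2]]; d <- ej[e[2]]
      if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      ## proposed new edges: (a, d), (c_, b)
      if (length(unique(c(a, b, c_, d))) < 4) next
      if (adj[a, d] || adj[c_, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c_, d] <- adj[d, c_] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c_, b] <- adj[b, c_] <- TRUE
      ei[e[1]] <<- a; ej[e[1]] <<- d
      ei[e[2]] <<- c_; ej[e[2]] <<- b
      accepted <- accepted + 1L
    }
    accepted
  }
  accepted <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- ppi_network(tibble(protein_a = nodes[pmin(ei, ej)],
                            protein_b = nodes[pmax(ei, ej)]))
  ## preserve isolated nodes, if any
  if (!setequal(out$nodes, nodes)) {
    out$nodes <- nodes
    out <- ppi_net_with_nodes(out$edges, nodes)
  }
  attr(out, "swaps_attempted") <- as.integer(n_swaps)
  attr(out, "swaps_accepted") <- accepted
  out
}

ppi_net_with_nodes <- function(edges, nodes) {
  nodes <- sort(nodes)
  g <- as_ppi_igraph(nodes, edges)
  comp <- igraph::components(g)$membership
  structure(list(nodes = nodes,
                 edges = dplyr::arrange(edges, .data$from, .data$to),
                 component = setNames(as.integer(comp), nodes)),
            class = "ppi_net")
}

#' @export
rewire_degree_preserving.bipartite_net <- function(net, n_swaps = NULL,
                                                   seed = NULL) {
  m <- nrow(net$edges)
  if (m < 2) {
    warn("network has fewer than 2 edges; returned unchanged.")
    return(net)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  left <- net$mirnas
  right <- net$targets
  ei <- match(net$edges$mirna, left)
  ej <- match(net$edges$target, right)
  run <- function() {
    adj <- matrix(FALSE, length(left), length(right))
    adj[cbind(ei, ej)] <- TRUE
    accepted <- 0L
    for (it in seq_len(n_swaps)) {
      e <- sample.int(m, 2)
      l1 <- ei[e[1]]; r1 <- ej[e[1]]
      l2 <- ei[e[2]]; r2 <- ej[e[2]]
      if (l1 == l2 || r1 == r2) next
      if (adj[l1, r2] || adj[l2, r1]) next
      adj[l1, r1] <- FALSE
      adj[l2, r2] <- FALSE
      adj[l1, r2] <- TRUE
      adj[l2, r1] <- TRUE
      ej[e[1]] <<- r2
      ej[e[2]] <<- r1
      accepted <- accepted + 1L
    }
    accepted
  }
  accepted <- if (is.null(seed)) run() else with_seed(seed, run())
  edges <- tibble(mirna = left[ei], target = right[ej]) |>
    dplyr::arrange(.data$mirna, .data$target)
  out <- structure(list(edges = edges, mirnas = net$mirnas,
                        targets = net$targets, direction = net$direction),
                   class = "bipartite_net")
  attr(out, "swaps_attempted") <- as.integer(n_swaps)
  attr(out, "swaps_accepted") <- accepted
  out
}

null_measures <- list(
  ppi_net = list(
    degree = function(net) node_degrees(net),
    betweenness = function(net) betweenness_centrality(net),
    bridging = function(net) {
      br <- bridging_centrality(net)
      setNames(br$bridging, br$node)
    },
    centroid = function(net) centroid_centrality(net)
  ),
  bipartite_net = list(
    degree = function(net) c(mirna_degrees(net), target_edge_degrees(net)),
    mirna_degree = function(net) mirna_degrees(net),
    target_degree = function(net) target_edge_degrees(net)
  )
)

#' Null distribution of a network measure under degree-preserving rewiring
#'
#' Generates `n_random` rewired replicates of the network (replicate i uses
#' seed `seed + i`) and evaluates the chosen measure on each, giving the
#' randomized-network reference distribution against which observed
#' topological values are judged (violin-plot style). Upper-tail empirical
#' p-values per node use the `(r + 1) / (n + 1)` rule.
#'
#' @param net A [ppi_network()] or [build_bipartite()] network.
#' @param measure Measure name; one of `"degree"`, `"betweenness"`,
#'   `"bridging"`, `"centroid"` for PPI networks, or `"degree"`,
#'   `"mirna_degree"`, `"target_degree"` for bipartite networks.
#' @param n_random Number of randomized replicates (>= 1).
#' @param seed Base integer seed.
#' @param n_swaps Swap attempts per replicate (default `10 * n_edges`).
#' @return An object of class `null_summary`; see [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "b", "c", "d"),
#'                                   protein_b = c("b", "c", "d", "a")))
#' ns <- null_distribution(net, "betweenness", n_random = 5, seed = 1)
#' glance(ns)
#' @export
null_distribution <- function(net, measure, n_random = 100, seed = 1L,
                              n_swaps = NULL) {
  cls <- class(net)[1]
  reg <- null_measures[[cls]]
  if (is.null(reg))
    abort(sprintf("no null measures registered for class `%s`.", cls))
  if (!measure %in% names(reg))
    abort(sprintf("unknown measure `%s`; registered measures for %s: %s",
                  measure, cls, paste(names(reg), collapse = ", ")))
  if (n_random < 1) abort("`n_random` must be >= 1.")
  f <- reg[[measure]]
  observed <- f(net)
  nulls <- matrix(NA_real_, nrow = n_random, ncol = length(observed),
                  dimnames = list(NULL, names(observed)))
  for (i in seq_len(n_random)) {
    r_net <- rewire_degree_preserving(net, n_swaps = n_swaps,
                                      seed = stage_seed(seed, paste0("null", i)))
    nulls[i, ] <- f(r_net)[names(observed)]
  }
  p_upper <- (colSums(sweep(nulls, 2, observed, `>=`)) + 1) / (n_random + 1)
  structure(list(measure = measure, observed = observed, nulls = nulls,
                 p_upper = setNames(p_upper, names(observed)),
                 scheme = "degree-preserving double-edge swap",
                 seed = seed, n_random = n_random,
                 n_swaps = n_swaps %||% (10L * edge_count(net))),
            class = "null_summary")
}

edge_count <- function(net) nrow(net$edges)

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> measure `%s`, %d randomizations (%s)\n",
              x$measure, x$n_random, x$scheme))
  cat(sprintf("  %d node(s); min upper-tail empirical p = %.4g\n",
              length(x$observed), min(x$p_upper)))
  invisible(x)
}

#' Empirical p-value against a randomization null
#'
#' Rank-based tail probability `(r + 1) / (n + 1)` of an observed statistic
#' in a null sample, where `r` counts null values at least as extreme as the
#' observed one in the chosen tail. The two-sided value doubles the smaller
#' one-sided value (capped at 1).
#'
#' @param observed Observed scalar statistic.
#' @param null_values Numeric sample from the null.
#' @param tail `"upper"`, `"lower"`, or `"two_sided"`.
#' @return Empirical p-value in (0, 1].
#' @examples
#' empirical_pvalue(10, 1:99, "upper")
#' @export
empirical_pvalue <- function(observed, null_values,
                             tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  if (!length(null_values)) abort("`null_values` must be non-empty.")
  n <- length(null_values)
  p_up <- (sum(null_values >= observed) + 1) / (n + 1)
  p_lo <- (sum(null_values <= observed) + 1) / (n + 1)
  switch(tail,
         upper = p_up,
         lower = p_lo,
         two_sided = min(1, 2 * min(p_up, p_lo)))
}
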