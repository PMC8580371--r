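## --- PPI edge filtering, centralities, consensus hub selection ---

#' Filter PPI edges by evidence-channel scores
#'
#' Retains an interaction when its score strictly exceeds the configured
#' threshold in at least one channel (`mode = "any"`, default) or in every
#' channel (`mode = "all"`). Defaults follow the evidence thresholds used
#' for experimentally/database-annotated interactions: experiments > 0.0031,
#' databases > 0.36. Output is canonicalized (unordered pairs), self-loops
#' are dropped, and duplicate pairs are collapsed (keeping the per-channel
#' maximum score).
#'
#' @param edges PPI edge table with columns `protein_a`, `protein_b`, plus
#'   one numeric column per evidence channel.
#' @param thresholds Named numeric vector mapping channel name to its strict
#'   minimum score.
#' @param mode `"any"` (union of channels) or `"all"` (intersection).
#' @return The filtered, canonicalized edge table.
#' @examples
#' ppi <- tibble::tibble(protein_a = "A", protein_b = "B",
#'                       experiments = 0.5, databases = 0)
#' filter_ppi_edges(ppi)
#' @export
filter_ppi_edges <- function(edges,
                             thresholds = c(experiments = 0.0031,
                                            databases = 0.36),
                             mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!all(c("protein_a", "protein_b") %in% names(edges)))
    abort("`edges` must have columns `protein_a` and `protein_b`.")
  if (!length(thresholds) || is.null(names(thresholds)))
    abort("`thresholds` must be a non-empty named numeric vector.")
  channels <- names(thresholds)
  available <- setdiff(names(edges)[vapply(edges, is.numeric, logical(1))],
                       c("protein_a", "protein_b"))
  unknown <- setdiff(channels, names(edges))
  if (length(unknown))
    abort(sprintf("unknown channel(s) %s; available channels: %s",
                  paste(unknown, collapse = ", "),
                  paste(available, collapse = ", ")))
  pass <- vapply(channels,
                 function(ch) edges[[ch]] > thresholds[[ch]],
                 logical(nrow(edges)))
  if (nrow(edges) == 1) pass <- matrix(pass, nrow = 1)
  keep <- if (mode == "any") rowSums(pass) > 0 else rowSums(pass) == length(channels)
  out <- edges[keep & edges$protein_a != edges$protein_b, , drop = FALSE]
  a <- pmin(out$protein_a, out$protein_b)
  b <- pmax(out$protein_a, out$protein_b)
  out$protein_a <- a
  out$protein_b <- b
  out |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), max),
                     .groups = "drop") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Construct an undirected simple PPI network
#'
#' Builds the simple (loop-free, de-duplicated) undirected graph from an
#' edge table, typically the output of [filter_ppi_edges()].
#'
#' @param edges Edge table with columns `protein_a`, `protein_b`.
#' @return An object of class `ppi_net`: list with `nodes` (sorted character
#'   vector), `edges` (tibble `from`/`to`, canonical), and `component`
#'   (named integer membership).
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("A", "B"),
#'                                   protein_b = c("B", "C")))
#' net$nodes
#' @export
ppi_network <- function(edges) {
  if (!all(c("protein_a", "protein_b") %in% names(edges)))
    abort("`edges` must have columns `protein_a` and `protein_b`.")
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  keep <- a != b
  e <- dplyr::distinct(tibble(from = a[keep], to = b[keep]))
  nodes <- sort(unique(c(e$from, e$to)))
  g <- as_ppi_igraph(nodes, e)
  comp <- igraph::components(g)$membership
  structure(list(nodes = nodes,
                 edges = dplyr::arrange(e, .data$from, .data$to),
                 component = setNames(as.integer(comp), nodes)),
            class = "ppi_net")
}

as_ppi_igraph <- function(nodes, edges) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$from, nodes),
                                    match(edges$to, nodes)))
  g
}

#' @export
print.ppi_net <- function(x, ...) {
  cat(sprintf("<ppi_net> %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), nrow(x$edges),
              if (length(x$component)) max(x$component) else 0L))
  invisible(x)
}

node_degrees <- function(net) {
  d <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  setNames(as.integer(d), net$nodes)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness for an undirected simple graph:
#' for each node, the sum over unordered node pairs (endpoints excluded) of
#' the fraction of shortest paths passing through it. Computed per connected
#' component by Brandes' single-source dependency accumulation (compiled).
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector of betweenness values over `net$nodes`.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "c"),
#'                                   protein_b = c("c", "b")))
#' betweenness_centrality(net)
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  n <- length(net$nodes)
  if (n == 0) return(setNames(numeric(0), character(0)))
  cb <- cpp_betweenness(n,
                        match(net$edges$from, net$nodes) - 1L,
                        match(net$edges$to, net$nodes) - 1L)
  setNames(cb, net$nodes)
}

#' Bridging coefficient and bridging centrality
#'
#' The bridging coefficient of a node is the inverse of its degree divided by
#' the sum of inverse degrees of its neighbours; bridging centrality is the
#' product of betweenness and the bridging coefficient, high for nodes that
#' connect otherwise weakly linked modules. Isolated nodes get coefficient 0.
#'
#' @param net A [ppi_network()].
#' @param betweenness Optional precomputed [betweenness_centrality()] vector.
#' @return A tibble with columns `node`, `bridging_coef`, `bridging`.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "a", "a", "a"),
#'                                   protein_b = c("b", "c", "d", "e")))
#' bridging_centrality(net)
#' @export
bridging_centrality <- function(net, betweenness = NULL) {
  stopifnot(inherits(net, "ppi_net"))
  if (is.null(betweenness)) betweenness <- betweenness_centrality(net)
  deg <- node_degrees(net)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  nbr_sum <- setNames(numeric(length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]
    nbr_sum[f] <- nbr_sum[f] + inv[t]
    nbr_sum[t] <- nbr_sum[t] + inv[f]
  }
  coef <- ifelse(deg > 0, inv / nbr_sum, 0)
  if (any(deg == 0))
    inform(sprintf("%d isolated node(s) assigned bridging coefficient 0.",
                   sum(deg == 0)))
  tibble(node = net$nodes,
         bridging_coef = unname(coef),
         bridging = unname(betweenness[net$nodes] * coef))
}

#' Centroid centrality
#'
#' For nodes v, w in the same connected component let gamma_v(w) count the
#' other nodes strictly closer to v than to w. The centroid value of v is the
#' minimum over all w of gamma_v(w) - gamma_w(v): positive for nodes near the
#' topological centre of their component, negative for peripheral ones.
#' Computed within each component; singleton components get 0.
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector of centroid values over `net$nodes`.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "c"),
#'                                   protein_b = c("c", "b")))
#' centroid_centrality(net)
#' @export
centroid_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  n <- length(net$nodes)
  out <- setNames(numeric(n), net$nodes)
  if (n == 0) return(out)
  g <- as_ppi_igraph(net$nodes, net$edges)
  for (cid in unique(net$component)) {
    idx <- which(net$component == cid)
    if (length(idx) == 1) { out[idx] <- 0; next }
    D <- igraph::distances(g, v = idx, to = idx)
    k <- length(idx)
    ## S[v, w] = #{u : d(u, v) < d(u, w)}; u = v always counts, u = w never,
    ## so gamma_v(w) = S[v, w] - 1 and the -1 cancels in the difference.
    S <- vapply(seq_len(k), function(w) colSums(D < D[, w]), numeric(k))
    f <- S - t(S)
    diag(f) <- Inf
    out[idx] <- apply(f, 1, min)
  }
  out
}

#' Full centrality report for a PPI network
#'
#' Computes degree, betweenness, bridging coefficient, bridging centrality
#' and centroid centrality for every node, together with the network-wide
#' mean of each measure (stored as the `"means"` attribute and retrievable
#' via [glance()]).
#'
#' @param net A [ppi_network()].
#' @return A tibble of class `centrality_report` with columns `node`,
#'   `degree`, `betweenness`, `bridging_coef`, `bridging`, `centroid`.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "c"),
#'                                   protein_b = c("c", "b")))
#' centrality_report(net)
#' @export
centrality_report <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  cb <- betweenness_centrality(net)
  br <- bridging_centrality(net, cb)
  cen <- centroid_centrality(net)
  out <- tibble(node = net$nodes,
                degree = unname(node_degrees(net)),
                betweenness = unname(cb),
                bridging_coef = br$bridging_coef,
                bridging = br$bridging,
                centroid = unname(cen))
  attr(out, "means") <- c(degree = mean(out$degree),
                          betweenness = mean(out$betweenness),
                          bridging = mean(out$bridging),
                          centroid = mean(out$centroid))
  class(out) <- c("centrality_report", class(out))
  out
}

#' Consensus hub selection
#'
#' A node is a hub when its centrality strictly exceeds the network-wide mean
#' for the required centralities — in all of them (`mode = "all"`, the
#' conservative consensus default) or in at least one (`mode = "any"`).
#'
#' @param report A [centrality_report()].
#' @param required Character subset of
#'   `c("betweenness", "bridging", "centroid", "degree")`.
#' @param mode `"all"` or `"any"`.
#' @return A tibble of class `hub_set`: one row per hub with its centrality
#'   values and logical `pass_*` columns; attributes `means`, `mode`,
#'   `required`.
#' @examples
#' net <- ppi_network(tibble::tibble(protein_a = c("a", "a", "a", "a"),
#'                                   protein_b = c("b", "c", "d", "e")))
#' select_hubs(centrality_report(net))
#' @export
select_hubs <- function(report,
                        required = c("betweenness", "bridging", "centroid"),
                        mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (!inherits(report, "centrality_report") || nrow(report) == 0)
    abort("`report` must be a non-empty centrality_report.")
  required <- match.arg(required,
                        c("betweenness", "bridging", "centroid", "degree"),
                        several.ok = TRUE)
  means <- attr(report, "means", exact = TRUE)
  pass <- vapply(required, function(m) report[[m]] > means[[m]],
                 logical(nrow(report)))
  if (nrow(report) == 1) pass <- matrix(pass, nrow = 1)
  colnames(pass) <- paste0("pass_", required)
  is_hub <- if (mode == "all") rowSums(pass) == length(required)
            else rowSums(pass) > 0
  out <- dplyr::bind_cols(as_tibble(report)[, unique(c("node", "degree", required))],
                          as_tibble(as.data.frame(pass)))
  out <- out[is_hub, , drop = FALSE]
  attr(out, "means") <- means
  attr(out, "mode") <- mode
  attr(out, "required") <- required
  class(out) <- c("hub_set", class(out))
  out
}

#' Annotate hubs with their miRNA-targeting counts
#'
#' For each hub gene, counts the distinct EV-miRNAs targeting its transcript
#' in the bipartite miRNA-target network (0 when the gene is absent), the
#' quantity rendered as gene-name size in the hub network figure.
#'
#' @param hubs A [select_hubs()] result.
#' @param net A [build_bipartite()] network sharing the gene-symbol
#'   namespace with the PPI nodes.
#' @return `hubs` with an added integer column `mirna_targeting`.
#' @examples
#' de <- tibble::tibble(transcript = "A", log2_fc = 1, direction = "up")
#' ints <- tibble::tibble(mirna = c("m1", "m2"), target = "A")
#' bip <- build_bipartite(ints, de, c("m1", "m2"))
#' ppi <- ppi_network(tibble::tibble(protein_a = c("A", "A", "A", "A"),
#'                                   protein_b = c("B", "C", "D", "E")))
#' crosslink_hubs(select_hubs(centrality_report(ppi)), bip)
#' @export
crosslink_hubs <- function(hubs, net) {
  stopifnot(inherits(hubs, "hub_set"), inherits(net, "bipartite_net"))
  deg <- target_edge_degrees(net)
  counts <- as.integer(deg[hubs$node])
  counts[is.na(counts)] <- 0L
  hubs$mirna_targeting <- counts
  hubs
}
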