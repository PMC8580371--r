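## Independent brute-force oracles for graph centralities, kept deliberately
## naive: betweenness by enumerating every simple path, distances by
## Floyd-Warshall, centroid and bridging by literal definition loops.

oracle_adjacency <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- TRUE
    A[edges[i, 2], edges[i, 1]] <- TRUE
  }
  A
}

## all simple paths s -> t by depth-first search
oracle_simple_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (A[v, w] && !visited[w]) {
        visited[w] <- TRUE
        walk(w, visited, c(path, w))
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  walk(s, visited, s)
  paths
}

oracle_betweenness <- function(n, edges) {
  A <- oracle_adjacency(n, edges)
  cb <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_simple_paths(A, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        cb[v] <- cb[v] + through / sigma
      }
    }
  }
  cb
}

oracle_distances <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    D[edges[i, 1], edges[i, 2]] <- 1
    D[edges[i, 2], edges[i, 1]] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_centroid <- function(n, edges) {
  D <- oracle_distances(n, edges)
  out <- numeric(n)
  for (v in seq_len(n)) {
    same <- which(is.finite(D[v, ]))
    ws <- setdiff(same, v)
    if (!length(ws)) { out[v] <- 0; next }
    fs <- vapply(ws, function(w) {
      us <- setdiff(same, c(v, w))
      g_vw <- sum(D[us, v] < D[us, w])
      g_wv <- sum(D[us, w] < D[us, v])
      g_vw - g_wv
    }, numeric(1))
    out[v] <- min(fs)
  }
  out
}

oracle_bridging <- function(n, edges, cb) {
  deg <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    nbrs[[a]] <- c(nbrs[[a]], b); nbrs[[b]] <- c(nbrs[[b]], a)
  }
  coef <- vapply(seq_len(n), function(v) {
    if (deg[v] == 0) return(0)
    (1 / deg[v]) / sum(1 / deg[nbrs[[v]]])
  }, numeric(1))
  coef * cb
}

## random connected graph on 3..max_n nodes (edges as 2-column matrix)
random_connected_graph <- function(max_n = 7) {
  repeat {
    n <- sample(3:max_n, 1)
    p <- runif(1, 0.3, 0.9)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) < n - 1) next
    edges <- pairs[keep, , drop = FALSE]
    if (all(is.finite(oracle_distances(n, edges)))) return(list(n = n, edges = edges))
  }
}

## build a ppi_net from an integer edge matrix, with zero-padded node names
## so lexicographic node order matches the integer order
ppi_from_edges <- function(n, edges) {
  ids <- sprintf("n%02d", seq_len(n))
  ppi_network(tibble::tibble(protein_a = ids[edges[, 1]],
                             protein_b = ids[edges[, 2]]))
}

## centrality vectors of a ppi_net re-ordered to integer node order
net_centralities <- function(net) {
  rep <- centrality_report(net)
  list(betweenness = rep$betweenness, bridging = rep$bridging,
       centroid = rep$centroid, nodes = rep$node)
}

## small bipartite fixture builders
bip_from_pairs <- function(mirnas, de, pairs) {
  ints <- tibble::tibble(mirna = pairs[[1]], target = pairs[[2]])
  build_bipartite(ints, de, mirnas)
}

de_fixture <- function(n_up, n_down) {
  tibble::tibble(
    transcript = sprintf("g%03d", seq_len(n_up + n_down)),
    log2_fc = c(rep(1, n_up), rep(-1, n_down)),
    direction = rep(c("up", "down"), c(n_up, n_down))
  )
}
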