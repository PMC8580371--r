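test_that("PPI evidence filter applies strict per-channel thresholds", {
  edges <- tibble::tibble(
    protein_a = c("A", "B", "C", "D", "E"),
    protein_b = c("B", "C", "D", "E", "A"),
    experiments = c(0.5, 0.0031, 0.001, 0.9, 0),
    databases = c(0, 0.36, 0.5, 0.5, 0.1)
  )
  kept_any <- filter_ppi_edges(edges)
  ## union semantics: strict > in at least one channel
  expect_setequal(kept_any$protein_a, c("A", "C", "D"))
  kept_all <- filter_ppi_edges(edges, mode = "all")
  expect_equal(nrow(kept_all), 1)
  expect_equal(kept_all$protein_a, "D")

  expect_error(filter_ppi_edges(edges, c(textmining = 0.5)),
               "available channels")
})

test_that("PPI filter canonicalizes, de-duplicates and drops self-loops", {
  edges <- tibble::tibble(
    protein_a = c("B", "A", "C"),
    protein_b = c("A", "B", "C"),
    experiments = c(0.5, 0.7, 0.9),
    databases = c(0.1, 0.2, 0.3)
  )
  out <- filter_ppi_edges(edges)
  expect_equal(nrow(out), 1)
  expect_equal(out$protein_a, "A")
  expect_equal(out$protein_b, "B")
  expect_equal(out$experiments, 0.7)

  withr::with_seed(3, {
    tbl <- tibble::tibble(
      protein_a = sample(LETTERS[1:8], 40, replace = TRUE),
      protein_b = sample(LETTERS[1:8], 40, replace = TRUE),
      experiments = runif(40), databases = runif(40)
    )
  })
  out <- filter_ppi_edges(tbl, c(experiments = 0.4, databases = 0.7))
  manual_keep <- (tbl$experiments > 0.4 | tbl$databases > 0.7) &
    tbl$protein_a != tbl$protein_b
  manual_pairs <- unique(paste(pmin(tbl$protein_a[manual_keep],
                                    tbl$protein_b[manual_keep]),
                               pmax(tbl$protein_a[manual_keep],
                                    tbl$protein_b[manual_keep])))
  expect_setequal(paste(out$protein_a, out$protein_b), manual_pairs)
})

test_that("hand-computed centralities: path, cycle, star, complete graphs", {
  ## P3: a - c - b
  p3 <- ppi_network(tibble::tibble(protein_a = c("a", "c"),
                                   protein_b = c("c", "b")))
  cb <- betweenness_centrality(p3)
  expect_equal(unname(cb[c("a", "b", "c")]), c(0, 0, 1))
  cen <- centroid_centrality(p3)
  expect_equal(unname(cen[c("a", "b", "c")]), c(-1, -1, 1))

  ## 4-cycle
  c4 <- ppi_network(tibble::tibble(protein_a = c("a", "b", "c", "d"),
                                   protein_b = c("b", "c", "d", "a")))
  cb4 <- betweenness_centrality(c4)
  expect_equal(unname(cb4), rep(0.5, 4))
  br4 <- bridging_centrality(c4, cb4)
  expect_equal(br4$bridging_coef, rep(0.5, 4))
  expect_equal(br4$bridging, rep(0.25, 4))

  ## star with 4 leaves
  star <- ppi_network(tibble::tibble(protein_a = rep("hub", 4),
                                     protein_b = paste0("leaf", 1:4)))
  cbs <- betweenness_centrality(star)
  expect_equal(unname(cbs["hub"]), 6)
  expect_equal(unname(cbs[paste0("leaf", 1:4)]), rep(0, 4))
  brs <- bridging_centrality(star, cbs)
  expect_equal(brs$bridging_coef[brs$node == "hub"], 1 / 16)
  expect_equal(brs$bridging[brs$node == "hub"], 0.375)
  expect_equal(brs$bridging[brs$node != "hub"], rep(0, 4))
  cens <- centroid_centrality(star)
  expect_equal(unname(cens["hub"]), 3)

  ## complete graphs: all betweenness and centroid zero
  for (n in c(4, 6)) {
    pairs <- t(combn(n, 2))
    kn <- ppi_from_edges(n, pairs)
    expect_equal(unname(betweenness_centrality(kn)), rep(0, n))
    expect_equal(unname(centroid_centrality(kn)), rep(0, n))
  }
})

test_that("centralities equal brute-force enumeration on random graphs", {
  withr::with_seed(97, {
    for (i in 1:30) {
      g <- random_connected_graph(7)
      net <- ppi_from_edges(g$n, g$edges)
      got <- net_centralities(net)
      ord <- match(sprintf("n%02d", seq_len(g$n)), got$nodes)
      cb_oracle <- oracle_betweenness(g$n, g$edges)
      expect_equal(got$betweenness[ord], cb_oracle, tolerance = 1e-9)
      expect_equal(got$bridging[ord],
                   oracle_bridging(g$n, g$edges, cb_oracle),
                   tolerance = 1e-9)
      expect_equal(got$centroid[ord], oracle_centroid(g$n, g$edges),
                   tolerance = 1e-9)
    }
  })
})

test_that("betweenness agrees with an independent library implementation", {
  withr::with_seed(55, {
    for (i in 1:10) {
      n <- sample(10:30, 1)
      g <- igraph::sample_gnp(n, 0.2)
      el <- igraph::as_edgelist(g, names = FALSE)
      if (nrow(el) < 2) next
      net <- ppi_from_edges(n, el)
      ref <- igraph::betweenness(
        igraph::graph_from_edgelist(el, directed = FALSE),
        directed = FALSE, normalized = FALSE)
      got <- betweenness_centrality(net)
      present <- sprintf("n%02d", seq_len(max(el)))
      idx <- which(present %in% names(got))
      expect_equal(unname(got[present[idx]]), unname(ref[idx]),
                   tolerance = 1e-9)
    }
  })
})

test_that("relabeling nodes permutes centralities identically", {
  withr::with_seed(71, {
    g <- random_connected_graph(7)
  })
  net <- ppi_from_edges(g$n, g$edges)
  rep1 <- centrality_report(net)
  perm <- sample(g$n)
  relabeled <- matrix(perm[g$edges], ncol = 2)
  net2 <- ppi_from_edges(g$n, relabeled)
  rep2 <- centrality_report(net2)
  for (measure in c("betweenness", "bridging", "centroid")) {
    v1 <- setNames(rep1[[measure]], rep1$node)
    v2 <- setNames(rep2[[measure]], rep2$node)
    expect_equal(unname(v2[sprintf("n%02d", perm)]),
                 unname(v1[sprintf("n%02d", seq_len(g$n))]),
                 tolerance = 1e-9)
  }
})

test_that("adding a pendant leaf never decreases betweenness", {
  withr::with_seed(83, {
    for (i in 1:10) {
      g <- random_connected_graph(6)
      v <- sample(g$n, 1)
      net <- ppi_from_edges(g$n, g$edges)
      before <- betweenness_centrality(net)[sprintf("n%02d", v)]
      aug <- rbind(g$edges, c(v, g$n + 1))
      net2 <- ppi_from_edges(g$n + 1, aug)
      after <- betweenness_centrality(net2)[sprintf("n%02d", v)]
      expect_gte(after + 1e-12, before)
    }
  })
})

test_that("a hub wired to every node of a path background dominates betweenness", {
  path_edges <- tibble::tibble(protein_a = sprintf("p%d", 1:5),
                               protein_b = sprintf("p%d", 2:6))
  hub_edges <- tibble::tibble(protein_a = "hub",
                              protein_b = sprintf("p%d", 1:6))
  net <- ppi_network(dplyr::bind_rows(path_edges, hub_edges))
  cb <- betweenness_centrality(net)
  expect_equal(names(which.max(cb)), "hub")
})

test_that("consensus hub selection uses strict above-mean rules", {
  star <- ppi_network(tibble::tibble(protein_a = rep("hub", 4),
                                     protein_b = paste0("leaf", 1:4)))
  rep_ <- centrality_report(star)
  hubs <- select_hubs(rep_)
  expect_equal(hubs$node, "hub")

  ## identical values everywhere -> nothing strictly exceeds the mean
  c4 <- ppi_network(tibble::tibble(protein_a = c("a", "b", "c", "d"),
                                   protein_b = c("b", "c", "d", "a")))
  expect_equal(nrow(select_hubs(centrality_report(c4))), 0)

  ## mode=all is a subset of mode=any
  withr::with_seed(29, {
    g <- random_connected_graph(7)
  })
  rep_r <- centrality_report(ppi_from_edges(g$n, g$edges))
  all_h <- select_hubs(rep_r, mode = "all")$node
  any_h <- select_hubs(rep_r, mode = "any")$node
  expect_true(all(all_h %in% any_h))
})

test_that("hub crosslink counts bipartite targeting degree", {
  de <- de_fixture(2, 0)
  ints <- tibble::tibble(mirna = c("m1", "m2", "m3"),
                         target = c("g001", "g001", "g002"))
  bip <- build_bipartite(ints, de, paste0("m", 1:3))
  star <- ppi_network(tibble::tibble(protein_a = rep("g001", 4),
                                     protein_b = c("g002", "x", "y", "z")))
  hubs <- crosslink_hubs(select_hubs(centrality_report(star)), bip)
  expect_equal(hubs$mirna_targeting[hubs$node == "g001"], 2L)

  ## hub absent from the bipartite net -> 0
  star2 <- ppi_network(tibble::tibble(protein_a = rep("absent", 4),
                                      protein_b = c("x", "y", "z", "w")))
  hubs2 <- crosslink_hubs(select_hubs(centrality_report(star2)), bip)
  expect_equal(hubs2$mirna_targeting, 0L)
})
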