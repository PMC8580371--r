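test_that("top-percent filter keeps the highest scores with boundary ties", {
  ladder <- tibble::tibble(mirna = "m", target = paste0("t", 1:10),
                           source = "db", score = 1:10)
  kept <- filter_top_percent(ladder, 20)
  expect_setequal(kept$score, c(9, 10))

  expect_identical(filter_top_percent(ladder, 100), ladder)

  tied <- tibble::tibble(mirna = "m", target = paste0("t", 1:5),
                         source = "db", score = c(5, 5, 5, 1, 1))
  expect_equal(filter_top_percent(tied, 20)$score, c(5, 5, 5))

  expect_error(filter_top_percent(ladder, 0), "pct")
})

test_that("top-percent filter works per source and spares unscored records", {
  ints <- dplyr::bind_rows(
    tibble::tibble(mirna = "m", target = paste0("a", 1:10),
                   source = "db1", score = 1:10),
    tibble::tibble(mirna = "m", target = paste0("b", 1:4),
                   source = "db2", score = c(100, 90, 10, 5)),
    tibble::tibble(mirna = "m", target = "validated",
                   source = "curated", score = NA_real_)
  )
  kept <- filter_top_percent(ints, 20)
  expect_setequal(kept$target[kept$source == "db1"], c("a9", "a10"))
  expect_setequal(kept$target[kept$source == "db2"], "b1")
  expect_true("validated" %in% kept$target)
})

test_that("bipartite construction restricts to DE targets and de-duplicates", {
  de <- de_fixture(2, 1)
  ints <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m2"),
    target = c("g001", "notDE", "g001", "g001"),
    source = c("db1", "db1", "db1", "db2")
  )
  net <- build_bipartite(ints, de, c("m1", "m2", "m3"))
  expect_s3_class(net, "bipartite_net")
  expect_equal(nrow(net$edges), 2)
  expect_false("notDE" %in% net$targets)
  deg <- degree_report(net, "mirna")
  expect_equal(deg$degree[deg$node == "m2"], 1)

  empty <- build_bipartite(ints[0, ], de, c("m1", "m2"))
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$mirnas, 2)

  up_only <- build_bipartite(ints, de, c("m1", "m2"), direction = "up")
  expect_true(all(up_only$targets %in% de$transcript[de$direction == "up"]))
})

test_that("degree handshake holds and duplication is idempotent", {
  withr::with_seed(41, {
    for (i in 1:10) {
      de <- de_fixture(8, 5)
      n_pairs <- 60
      ints <- tibble::tibble(
        mirna = sample(paste0("m", 1:6), n_pairs, replace = TRUE),
        target = sample(c(de$transcript, "offlist"), n_pairs, replace = TRUE)
      )
      net <- build_bipartite(ints, de, paste0("m", 1:6))
      d_l <- degree_report(net, "mirna", min_degree = -1)
      d_r <- degree_report(net, "target", min_degree = -1)
      expect_equal(sum(d_l$degree), nrow(net$edges))
      expect_equal(sum(d_r$degree), nrow(net$edges))

      dup <- build_bipartite(dplyr::bind_rows(ints, ints), de, paste0("m", 1:6))
      expect_identical(dup$edges, net$edges)

      ## brute-force degree oracle
      uniq <- unique(ints[ints$target %in% de$transcript, c("mirna", "target")])
      for (m in paste0("m", 1:6)) {
        expected <- sum(uniq$mirna == m)
        got <- d_l$degree[d_l$node == m]
        expect_equal(got, expected)
      }

      up_net <- build_bipartite(ints, de, paste0("m", 1:6), direction = "up")
      d_up <- mirna_deg <- degree_report(up_net, "mirna", min_degree = -1)
      for (m in paste0("m", 1:6))
        expect_lte(d_up$degree[d_up$node == m], d_l$degree[d_l$node == m])
    }
  })
})

test_that("degree report orders by degree then name and applies strict cutoff", {
  de <- de_fixture(5, 0)
  ints <- tibble::tibble(mirna = "m1", target = paste0("g00", 1:5))
  net <- build_bipartite(ints, de, "m1")
  expect_identical(degree_report(net, "mirna"),
                   tibble::tibble(node = "m1", degree = 5L))
  expect_equal(nrow(degree_report(net, "mirna", min_degree = 5)), 0)
  expect_equal(nrow(degree_report(net, "target", min_degree = 1)), 0)
})

test_that("student_t reproduces the pooled-variance formula", {
  out <- student_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(out$df, 4)

  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(student_t(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(student_t(1, c(1, 2)), "at least 2")

  withr::with_seed(17, {
    a <- rnorm(20); b <- rnorm(25, 1)
  })
  out <- student_t(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), 43), tolerance = 1e-12)
})

test_that("enrichment statistics count degrees, fractions and coverage", {
  ## constructed: every up-transcript degree 2, every down degree 1
  de <- de_fixture(3, 2)
  up_t <- de$transcript[de$direction == "up"]
  down_t <- de$transcript[de$direction == "down"]
  ints <- dplyr::bind_rows(
    tidyr::expand_grid(mirna = c("m1", "m2"), target = up_t),
    tibble::tibble(mirna = "m1", target = down_t)
  )
  net <- build_bipartite(ints, de, c("m1", "m2"))
  res <- enrichment_stats(net, de)
  expect_equal(res$ratio, 2)
  expect_equal(res$coverage_n, 5)
  expect_equal(res$coverage_fraction, 1)

  ## per-miRNA up-fraction: m1 has 3 up + 2 down of 5; with threshold 2 both
  ## miRNAs qualify only if degree > 2
  fr <- res$mirna_up_fractions
  expect_equal(fr$up_fraction[fr$mirna == "m1"], 3 / 5)
  expect_equal(fr$up_fraction[fr$mirna == "m2"], 1)
  expect_equal(res$mean_up_fraction, mean(c(3 / 5, 1)))

  ## miRNA with 3 up, 1 down -> fraction 0.75
  de2 <- de_fixture(3, 1)
  ints2 <- tibble::tibble(mirna = "mx", target = de2$transcript)
  res2 <- enrichment_stats(build_bipartite(ints2, de2, "mx"), de2)
  expect_equal(res2$mirna_up_fractions$up_fraction, 0.75)
})

test_that("zero-degree transcripts enter or leave the comparison by switch", {
  de <- de_fixture(2, 2)
  ints <- tibble::tibble(mirna = "m1", target = de$transcript[c(1, 3)])
  net <- build_bipartite(ints, de, "m1")
  with_zeros <- enrichment_stats(net, de)
  expect_equal(with_zeros$mean_degree_up, 0.5)
  expect_equal(with_zeros$mean_degree_down, 0.5)
  without <- enrichment_stats(net, de, include_zero_degree = FALSE)
  expect_equal(without$mean_degree_up, 1)
  expect_equal(without$mean_degree_down, 1)
})

test_that("one empty direction flags the result as degenerate", {
  de <- de_fixture(3, 0)
  ints <- tibble::tibble(mirna = "m1", target = de$transcript)
  net <- build_bipartite(ints, de, "m1")
  res <- enrichment_stats(net, de)
  expect_true(res$degenerate)
  expect_true(is.na(res$ratio))
  expect_true(is.na(res$t$p_value))
})

test_that("label permutation p follows the (r+1)/(n+1) rule", {
  ## strong separation: observed difference beats every permutation
  de <- de_fixture(5, 5)
  up_t <- de$transcript[de$direction == "up"]
  ints <- tidyr::expand_grid(mirna = paste0("m", 1:10), target = up_t)
  net <- build_bipartite(ints, de, paste0("m", 1:10))
  out <- label_permutation_test(net, de, n_perm = 99, seed = 1)
  expect_equal(out$p_value, 0.01)

  expect_error(label_permutation_test(net, de, n_perm = 0), "n_perm")

  ## permutation p and t-test p agree in order of magnitude on planted effect
  cfg <- sim_config(seed = 31)
  de_s <- simulate_de_table(cfg)
  ints_s <- simulate_interactions(paste0("m", 1:60), de_s, cfg)
  net_s <- build_bipartite(ints_s, de_s, paste0("m", 1:60))
  t_p <- enrichment_stats(net_s, de_s)$t$p_value
  perm_p <- label_permutation_test(net_s, de_s, n_perm = 199, seed = 2)$p_value
  expect_lt(t_p, 0.01)
  expect_lte(perm_p, 0.01)
})
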