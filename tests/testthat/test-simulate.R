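test_that("identical config yields identical artifacts", {
  cfg <- sim_config(n_mirnas_total = 120, ppi_n_nodes = 32,
                    n_planted_hubs = 1, seed = 11)
  a <- simulate_inputs(cfg)
  b <- simulate_inputs(cfg)
  expect_identical(a$ct_ev, b$ct_ev)
  expect_identical(a$ct_ic, b$ct_ic)
  expect_identical(a$de, b$de)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$ppi, b$ppi)
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(detect_fraction = 1.5), "detect_fraction")
  expect_error(sim_config(p_base = 0.6, enrichment_ratio = 2), "exceeds 1")
  expect_error(sim_config(n_up = 0), "n_up")
  expect_error(sim_config(ct_detect_mean = NaN), "ct_detect_mean")
  expect_error(sim_config(ppi_n_nodes = 3, n_planted_hubs = 2), "ppi_n_nodes")
})

test_that("detect_fraction = 0 puts every well at the sentinel floor", {
  prof <- simulate_ct_profiles(sim_config(n_mirnas_total = 40,
                                          detect_fraction = 0, seed = 3))
  expect_true(all(as.matrix(prof$ev[, -1]) == 40))
  expect_true(all(as.matrix(prof$ic[, -1]) == 40))
})

test_that("perfect correlation with zero noise makes compartments match up to offset", {
  cfg <- sim_config(n_mirnas_total = 100, detect_fraction = 0.5,
                    subject_sd = 0, ev_ic_correlation = 1, seed = 5)
  prof <- simulate_ct_profiles(cfg)
  rel_ev <- normalize_global_mean(prof$ev, detect_mirnas(prof$ev))
  rel_ic <- normalize_global_mean(prof$ic, detect_mirnas(prof$ic))
  expect_identical(rel_ev$mirna, rel_ic$mirna)
  for (s in names(rel_ev)[-1])
    expect_equal(rel_ev[[s]], rel_ic[[s]], tolerance = 1e-9)
})

test_that("planted compartment correlation is recovered on average", {
  rs <- vapply(1:30, function(s) {
    prof <- simulate_ct_profiles(sim_config(seed = s))
    rel_ev <- normalize_global_mean(prof$ev, detect_mirnas(prof$ev))
    rel_ic <- normalize_global_mean(prof$ic, detect_mirnas(prof$ic))
    compartment_correlation(rel_ev, rel_ic)$estimate
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.1)
})

test_that("DE table has the requested composition and consistent labels", {
  de <- simulate_de_table(sim_config(seed = 2))
  expect_equal(nrow(de), 360)
  expect_equal(sum(de$direction == "up"), 231)
  expect_equal(sum(de$direction == "down"), 129)
  expect_false(anyDuplicated(de$transcript) > 0)
  expect_identical(de$direction, ifelse(de$log2_fc > 0, "up", "down"))

  tiny <- simulate_de_table(sim_config(n_up = 1, n_down = 1, seed = 2))
  expect_equal(nrow(tiny), 2)
  expect_setequal(sign(tiny$log2_fc), c(1, -1))
})

test_that("interaction simulation respects the planted probabilities", {
  cfg <- sim_config(p_base = 0, enrichment_ratio = 2, seed = 4)
  de <- simulate_de_table(cfg)
  ints <- simulate_interactions(paste0("m", 1:20), de, cfg)
  dir_of <- setNames(de$direction, de$transcript)
  expect_true(all(dir_of[ints$target] == "up"))
  expect_true(all(ints$score > 0 & ints$score <= 100))

  cfg2 <- sim_config(p_base = 0.05, seed = 9)
  ints2 <- simulate_interactions(paste0("m", 1:60), de, cfg2)
  ## empirical rates close to p_up = 0.1 and p_base = 0.05
  n_up_pairs <- 60 * 231
  n_down_pairs <- 60 * 129
  rate_up <- sum(dir_of[ints2$target] == "up") / n_up_pairs
  rate_down <- sum(dir_of[ints2$target] == "down") / n_down_pairs
  expect_lt(abs(rate_up - 0.1), 0.01)
  expect_lt(abs(rate_down - 0.05), 0.01)
})

test_that("simulated PPI wires each planted hub to at least 30% of the background", {
  cfg <- sim_config(ppi_n_nodes = 40, n_planted_hubs = 2, seed = 8)
  ppi <- simulate_ppi(cfg)
  hubs <- attr(ppi, "planted_hubs")
  expect_length(hubs, 2)
  for (h in hubs) {
    deg <- sum(ppi$protein_a == h | ppi$protein_b == h)
    expect_gte(deg, 0.3 * 40)
  }
  expect_true(all(ppi$experiments >= 0 & ppi$experiments <= 1))
  expect_true(all(ppi$databases >= 0 & ppi$databases <= 1))
  expect_true(all(ppi$protein_a != ppi$protein_b))
})

test_that("uniform PPI background concentrates degrees near the expected mean", {
  cfg <- sim_config(ppi_n_nodes = 200, n_planted_hubs = 0,
                    ppi_model = list(model = "uniform", p = 0.05,
                                     hub_frac = c(0.7, 0.9)),
                    seed = 12)
  degs <- unlist(lapply(1:20, function(s) {
    cfg$seed <- s
    ppi <- simulate_ppi(cfg)
    tab <- table(c(ppi$protein_a, ppi$protein_b))
    as.integer(tab)
  }))
  expect_lt(abs(mean(degs) - 200 * 0.05), 1)
})
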