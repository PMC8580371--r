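## --- end-to-end pipeline driver ---

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: detectability
#' Ct < 35 in at least ceiling(0.8 x subjects) subjects, top 20% interaction
#' score filter, miRNA degree > 2 for the up-target fraction, PPI evidence
#' thresholds experiments > 0.0031 and databases > 0.36, consensus
#' (`mode = "all"`) hub selection over betweenness, bridging and centroid.
#' Inputs come either from a `simulate` block (a [sim_config()]) or from
#' file paths; the single `seed` drives every stochastic stage through
#' stable per-stage derived seeds.
#'
#' @param simulate A [sim_config()], or `NULL` when reading files. Its own
#'   seed is replaced by one derived from `seed`.
#' @param paths Named list of input paths (`ct_ev`, `ct_ic`, `de`,
#'   `interactions`, `ppi`); ignored when `simulate` is given.
#' @param ct_max,min_count Detectability rule (see [detect_mirnas()]).
#' @param top_pct Top-percent interaction score filter (see
#'   [filter_top_percent()]).
#' @param min_mirna_degree Strict miRNA degree threshold for the mean
#'   up-target fraction.
#' @param include_zero_degree Count edge-free DE transcripts as degree 0.
#' @param ppi_thresholds,ppi_channel_mode PPI evidence filter (see
#'   [filter_ppi_edges()]).
#' @param hub_required,hub_mode Consensus hub rule (see [select_hubs()]).
#' @param n_perm Permutations for the label-permutation test.
#' @param n_random,n_swaps Randomized-network null settings (see
#'   [null_distribution()]).
#' @param seed Single integer seed for the whole run.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(simulate = sim_config(), seed = 1)
#' @export
run_config <- function(simulate = NULL,
                       paths = NULL,
                       ct_max = 35,
                       min_count = NULL,
                       top_pct = 20,
                       min_mirna_degree = 2,
                       include_zero_degree = TRUE,
                       ppi_thresholds = c(experiments = 0.0031,
                                          databases = 0.36),
                       ppi_channel_mode = "any",
                       hub_required = c("betweenness", "bridging", "centroid"),
                       hub_mode = "all",
                       n_perm = 999,
                       n_random = 100,
                       n_swaps = NULL,
                       seed = 1L,
                       out_dir = NULL) {
  if (is.null(simulate)) {
    need <- c("ct_ev", "ct_ic", "de", "interactions", "ppi")
    if (is.null(paths) || !all(need %in% names(paths)))
      abort(sprintf("without a `simulate` block, `paths` must name: %s",
                    paste(need, collapse = ", ")))
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(simulate = simulate, paths = paths, ct_max = ct_max,
                 min_count = min_count, top_pct = top_pct,
                 min_mirna_degree = min_mirna_degree,
                 include_zero_degree = include_zero_degree,
                 ppi_thresholds = ppi_thresholds,
                 ppi_channel_mode = ppi_channel_mode,
                 hub_required = hub_required, hub_mode = hub_mode,
                 n_perm = n_perm, n_random = n_random, n_swaps = n_swaps,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: input simulation or reading, detectability
#' filtering, global-mean normalization, ranking, EV/intracellular
#' correlation, interaction score filtering, bipartite network construction
#' (both directions and up-only), enrichment statistics with t- and
#' permutation tests, PPI evidence filtering, centralities, consensus hub
#' selection, hub/miRNA cross-linking, and the randomized-network null for
#' hub betweenness. A stage failure aborts with the stage name; results
#' produced so far are written if `out_dir` is set.
#'
#' @param config A [run_config()].
#' @return A list bundle with all stage outputs, a `summary` list (also
#'   written as `summary.json` under `out_dir`), and the run `log`.
#' @examples
#' cfg <- run_config(simulate = sim_config(n_mirnas_total = 100,
#'                                         ppi_n_nodes = 24,
#'                                         n_planted_hubs = 1),
#'                   n_perm = 19, n_random = 3, seed = 1)
#' res <- run_pipeline(cfg)
#' res$summary$enrichment$ratio
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", "evmirnet", sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }
  seed <- config$seed
  note("evmirnet %s on R %s; run seed %d",
       as.character(utils::packageVersion("evmirnet")),
       paste(R.version$major, R.version$minor, sep = "."), seed)
  note("config hash %s", config_hash(config))

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- stage_seed(seed, "simulate")
      note("simulating inputs (derived seed %d)", sim$seed)
      simulate_inputs(sim, ct_max = config$ct_max,
                      min_count = config$min_count)
    } else {
      note("reading inputs from files")
      list(ct_ev = read_ct_matrix(config$paths$ct_ev, "EV"),
           ct_ic = read_ct_matrix(config$paths$ct_ic, "intracellular"),
           de = read_de_table(config$paths$de),
           interactions = read_interactions(config$paths$interactions),
           ppi = read_ppi_edges(config$paths$ppi))
    }
  })
  ppi_notes <- attr(inputs$ppi, "notes", exact = TRUE)
  if (!is.null(ppi_notes)) note("ppi input note: %s", ppi_notes)

  det_ev <- stage("detect", detect_mirnas(inputs$ct_ev, config$ct_max,
                                          config$min_count))
  det_ic <- stage("detect", detect_mirnas(inputs$ct_ic, config$ct_max,
                                          config$min_count))
  detected_ids <- det_ev$mirna[det_ev$detected]
  note("detected %d / %d EV miRNAs (Ct < %g rule)", length(detected_ids),
       nrow(det_ev), config$ct_max)

  rel_ev <- stage("normalize",
                  normalize_global_mean(inputs$ct_ev, det_ev, config$ct_max))
  rel_ic <- stage("normalize",
                  normalize_global_mean(inputs$ct_ic, det_ic, config$ct_max))
  ranking <- stage("rank", rank_mirnas(rel_ev))

  correlation <- stage("correlate", tryCatch(
    compartment_correlation(rel_ev, rel_ic),
    error = function(e) {
      note("compartment correlation unavailable: %s", conditionMessage(e))
      tibble(estimate = NA_real_, n = NA_integer_)
    }))

  interactions <- stage("filter_targets",
                        filter_top_percent(inputs$interactions,
                                           config$top_pct))
  note("interaction records: %d raw, %d after top-%g%% filter",
       nrow(inputs$interactions), nrow(interactions), config$top_pct)

  net_both <- stage("network",
                    build_bipartite(interactions, inputs$de, detected_ids,
                                    direction = "both"))
  net_up <- stage("network",
                  build_bipartite(interactions, inputs$de, detected_ids,
                                  direction = "up"))

  enrichment <- stage("enrichment",
                      enrichment_stats(net_both, inputs$de,
                                       config$min_mirna_degree,
                                       config$include_zero_degree))
  if (enrichment$degenerate)
    note("enrichment undefined: one DE direction has no transcripts in the comparison")
  perm <- stage("permutation", {
    if (enrichment$degenerate) {
      tibble(observed_diff = NA_real_, p_value = NA_real_,
             n_perm = as.integer(config$n_perm))
    } else {
      label_permutation_test(net_both, inputs$de, n_perm = config$n_perm,
                             seed = stage_seed(seed, "permutation"),
                             include_zero_degree = config$include_zero_degree)
    }
  })

  ppi_filtered <- stage("ppi_filter",
                        filter_ppi_edges(inputs$ppi, config$ppi_thresholds,
                                         config$ppi_channel_mode))
  ppi_net <- stage("ppi_network", ppi_network(ppi_filtered))
  note("PPI network: %d nodes, %d edges after evidence filter",
       length(ppi_net$nodes), nrow(ppi_net$edges))
  centralities <- stage("centralities", centrality_report(ppi_net))
  hubs <- stage("hubs", select_hubs(centralities, config$hub_required,
                                    config$hub_mode))
  hubs <- stage("crosslink", crosslink_hubs(hubs, net_up))
  note("%d consensus hub(s): %s", nrow(hubs),
       paste(utils::head(hubs$node, 10), collapse = ", "))

  nulls <- stage("nulls",
                 null_distribution(ppi_net, "betweenness",
                                   n_random = config$n_random,
                                   seed = stage_seed(seed, "nulls"),
                                   n_swaps = config$n_swaps))
  hub_null_p <- nulls$p_upper[hubs$node]

  summary <- list(
    seed = seed,
    detected = list(n = length(detected_ids), total = nrow(det_ev),
                    fraction = length(detected_ids) / nrow(det_ev)),
    compartment_correlation = list(pearson_r = correlation$estimate,
                                   n_shared = correlation$n),
    coverage = list(n = enrichment$coverage_n,
                    total = enrichment$coverage_total,
                    fraction = enrichment$coverage_fraction),
    enrichment = list(mean_degree_up = enrichment$mean_degree_up,
                      mean_degree_down = enrichment$mean_degree_down,
                      ratio = enrichment$ratio,
                      t_statistic = enrichment$t$statistic,
                      t_df = enrichment$t$df,
                      t_p_value = enrichment$t$p_value,
                      permutation_p = perm$p_value,
                      undefined = enrichment$degenerate,
                      mean_up_target_fraction = enrichment$mean_up_fraction),
    hubs = list(nodes = hubs$node,
                mirna_targeting = hubs$mirna_targeting,
                null_p_betweenness = unname(hub_null_p)),
    log = log_lines
  )

  bundle <- list(inputs = inputs, detected = det_ev, rel_ev = rel_ev,
                 rel_ic = rel_ic, ranking = ranking,
                 correlation = correlation, interactions = interactions,
                 net_both = net_both, net_up = net_up,
                 enrichment = enrichment, permutation = perm,
                 ppi_net = ppi_net, centralities = centralities,
                 hubs = hubs, nulls = nulls, summary = summary,
                 log = log_lines, config = config)

  if (!is.null(config$out_dir)) stage("write", write_bundle(bundle, config))
  bundle
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

write_bundle <- function(bundle, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ct_matrix(bundle$rel_ev, file.path(dir, "rel_expr_ev.csv"))
  write_ct_matrix(bundle$rel_ic, file.path(dir, "rel_expr_ic.csv"))
  readr::write_tsv(bundle$ranking, file.path(dir, "mirna_ranking.tsv"))
  readr::write_tsv(degree_report(bundle$net_both, "mirna"),
                   file.path(dir, "mirna_degree.tsv"))
  readr::write_tsv(degree_report(bundle$net_both, "target"),
                   file.path(dir, "target_degree.tsv"))
  write_edge_list(bundle$net_both, file.path(dir, "bipartite_both.tsv"))
  write_edge_list(bundle$net_up, file.path(dir, "bipartite_up.tsv"))
  write_graphml(bundle$net_up, file.path(dir, "bipartite_up.graphml"))
  write_edge_list(bundle$ppi_net, file.path(dir, "ppi_filtered.tsv"))
  write_graphml(bundle$ppi_net, file.path(dir, "ppi_filtered.graphml"))
  readr::write_tsv(as_tibble(bundle$centralities),
                   file.path(dir, "centrality_report.tsv"))
  jsonlite::write_json(as_tibble(bundle$hubs), file.path(dir, "hubs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(tidy(bundle$nulls), file.path(dir, "null_values.tsv"))
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}
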