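## --- miRNA-target bipartite network and enrichment statistics ---

validate_de_table <- function(de, arg = "de_table") {
  req <- c("transcript", "log2_fc", "direction")
  miss <- setdiff(req, names(de))
  if (length(miss))
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  if (anyDuplicated(de$transcript))
    abort(sprintf("duplicate transcript ids in `%s`.", arg))
  bad <- which(de$direction != ifelse(de$log2_fc > 0, "up", "down"))
  if (length(bad))
    abort(sprintf("`%s`: direction label disagrees with sign of log2_fc at row(s) %s",
                  arg, paste(utils::head(bad, 5), collapse = ", ")))
  invisible(de)
}

validate_interactions <- function(interactions, arg = "interactions") {
  req <- c("mirna", "target")
  miss <- setdiff(req, names(interactions))
  if (length(miss))
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  invisible(interactions)
}

#' Keep the top-scoring percentage of interaction records
#'
#' Within each source database, scored records are ranked by descending score
#' and the top `pct` percent retained; every record tied with the boundary
#' score is kept. Records without a score (`NA`) — e.g. purely
#' experimentally-validated entries — are retained unconditionally.
#'
#' @param interactions Interaction table with columns `mirna`, `target`, and
#'   optionally `source` and `score`.
#' @param pct Percentage in (0, 100] of scored records to keep per source.
#' @return The filtered interaction table (row order preserved).
#' @examples
#' ints <- tibble::tibble(mirna = "m", target = letters[1:10],
#'                        source = "db", score = 1:10)
#' filter_top_percent(ints, 20)
#' @export
filter_top_percent <- function(interactions, pct = 20) {
  validate_interactions(interactions)
  if (!is.numeric(pct) || pct <= 0 || pct > 100)
    abort("`pct` must be in (0, 100].")
  if (!"score" %in% names(interactions)) return(interactions)
  src <- if ("source" %in% names(interactions)) interactions$source
         else rep("all", nrow(interactions))
  keep <- rep(TRUE, nrow(interactions))
  for (s in unique(src)) {
    idx <- which(src == s & !is.na(interactions$score))
    if (!length(idx)) next
    scores <- interactions$score[idx]
    k <- ceiling(pct / 100 * length(scores))
    cutoff <- sort(scores, decreasing = TRUE)[k]
    keep[idx] <- scores >= cutoff
  }
  interactions[keep, , drop = FALSE]
}

#' Build the miRNA-target bipartite network
#'
#' Restricts the interaction table to the supplied miRNA set and to targets
#' present in the differential-expression table (optionally only the up- or
#' downregulated ones), collapses duplicate records across sources into
#' single undirected edges, and keeps interaction-free miRNAs as degree-0
#' nodes. Transcripts without any retained edge are not part of the network.
#'
#' @param interactions Interaction table (`mirna`, `target`, ...).
#' @param de DE table (`transcript`, `log2_fc`, `direction`).
#' @param mirnas Character vector of miRNA ids forming the left node set.
#' @param direction Which DE transcripts are eligible targets: `"both"`
#'   (default), `"up"`, or `"down"`.
#' @return An object of class `bipartite_net`: list with `edges` (tibble of
#'   unique `mirna`/`target` pairs), `mirnas` (all left nodes, sorted),
#'   `targets` (right nodes with at least one edge, sorted), `direction`.
#' @examples
#' de <- tibble::tibble(transcript = c("g1", "g2"),
#'                      log2_fc = c(1, -1), direction = c("up", "down"))
#' ints <- tibble::tibble(mirna = c("m1", "m1"), target = c("g1", "g3"))
#' build_bipartite(ints, de, mirnas = c("m1", "m2"))
#' @export
build_bipartite <- function(interactions, de, mirnas,
                            direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  validate_interactions(interactions)
  validate_de_table(de, "de")
  if (!length(mirnas)) abort("`mirnas` must be non-empty.")
  eligible <- if (direction == "both") de$transcript
              else de$transcript[de$direction == direction]
  edges <- interactions |>
    dplyr::filter(.data$mirna %in% .env$mirnas,
                  .data$target %in% .env$eligible) |>
    dplyr::distinct(.data$mirna, .data$target) |>
    dplyr::arrange(.data$mirna, .data$target)
  structure(
    list(edges = as_tibble(edges),
         mirnas = sort(unique(as.character(mirnas))),
         targets = sort(unique(edges$target)),
         direction = direction),
    class = "bipartite_net"
  )
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("<bipartite_net> %d miRNAs, %d targets (%s), %d edges\n",
              length(x$mirnas), length(x$targets), x$direction,
              nrow(x$edges)))
  invisible(x)
}

mirna_degrees <- function(net) {
  d <- table(factor(net$edges$mirna, levels = net$mirnas))
  setNames(as.integer(d), net$mirnas)
}

target_edge_degrees <- function(net) {
  d <- table(factor(net$edges$target, levels = net$targets))
  setNames(as.integer(d), net$targets)
}

#' Degree report for one side of the bipartite network
#'
#' Lists nodes whose degree is strictly greater than `min_degree`, in
#' descending degree order with lexicographic tie-break. For the miRNA side
#' all left nodes (including degree 0) are eligible; for the target side only
#' transcripts that are part of the network.
#'
#' @param net A [build_bipartite()] network.
#' @param side `"mirna"` or `"target"`.
#' @param min_degree Strict lower bound on reported degree.
#' @return A tibble with columns `node` and `degree`.
#' @examples
#' de <- tibble::tibble(transcript = paste0("g", 1:5),
#'                      log2_fc = 1, direction = "up")
#' ints <- tibble::tibble(mirna = "m1", target = paste0("g", 1:5))
#' degree_report(build_bipartite(ints, de, "m1"), "mirna")
#' @export
degree_report <- function(net, side = c("mirna", "target"), min_degree = 0) {
  stopifnot(inherits(net, "bipartite_net"))
  side <- match.arg(side)
  d <- if (side == "mirna") mirna_degrees(net) else target_edge_degrees(net)
  out <- tibble(node = names(d), degree = as.integer(d)) |>
    dplyr::filter(.data$degree > min_degree) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
  out
}

#' Classical two-sample Student's t-test
#'
#' Equal-variance (pooled) two-sample t with `n_a + n_b - 2` degrees of
#' freedom and a two-sided p-value, as used to compare the degree
#' distributions of up- and downregulated transcripts.
#'
#' @param group_a,group_b Numeric samples (each of size >= 2).
#' @return A one-row tibble with columns `statistic`, `df`, `p_value`.
#' @examples
#' student_t(c(1, 2, 3), c(2, 3, 4))
#' @export
student_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    abort("each group must have at least 2 observations.")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    abort("zero pooled variance: both groups are constant.")
  fit <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble(statistic = unname(fit$statistic),
         df = unname(fit$parameter),
         p_value = fit$p.value)
}

#' Targeting-enrichment statistics for up- vs downregulated transcripts
#'
#' Given the bipartite network built over both DE directions, compares the
#' per-transcript degree (number of distinct miRNAs targeting it) between
#' up- and downregulated transcripts: group means, their ratio, and a pooled
#' two-sample t-test. Also reports, per miRNA, the fraction of its targets
#' that are upregulated — averaged over miRNAs with degree strictly greater
#' than `min_mirna_degree` — and the coverage of the DE list (transcripts
#' with at least one miRNA edge).
#'
#' @param net A [build_bipartite()] network with `direction = "both"`.
#' @param de The DE table covering the network's targets.
#' @param min_mirna_degree Strict degree threshold for a miRNA to enter the
#'   mean up-target fraction (default 2, i.e. more than 2 targets).
#' @param include_zero_degree Count DE transcripts without any edge as degree
#'   0 in the group comparison (default `TRUE`); if `FALSE`, only transcripts
#'   in the network are compared.
#' @return An object of class `enrichment_result`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' de <- tibble::tibble(transcript = c("u1", "u2", "d1"),
#'                      log2_fc = c(1, 2, -1),
#'                      direction = c("up", "up", "down"))
#' ints <- tibble::tibble(mirna = c("m1", "m1", "m2"),
#'                        target = c("u1", "d1", "u1"))
#' res <- enrichment_stats(build_bipartite(ints, de, c("m1", "m2")), de)
#' glance(res)
#' @export
enrichment_stats <- function(net, de, min_mirna_degree = 2,
                             include_zero_degree = TRUE) {
  stopifnot(inherits(net, "bipartite_net"))
  validate_de_table(de, "de")
  if (net$direction != "both")
    abort("`net` must be built with direction = \"both\" for enrichment statistics.")
  extra <- setdiff(net$targets, de$transcript)
  if (length(extra))
    abort(sprintf("network targets missing from `de`: %s",
                  paste(utils::head(extra, 5), collapse = ", ")))

  deg_edge <- target_edge_degrees(net)
  target_deg <- tibble(transcript = de$transcript,
                       direction = de$direction,
                       degree = as.integer(deg_edge[de$transcript]))
  target_deg$degree[is.na(target_deg$degree)] <- 0L
  cmp <- if (include_zero_degree) target_deg
         else target_deg[target_deg$degree > 0, , drop = FALSE]

  up <- cmp$degree[cmp$direction == "up"]
  down <- cmp$degree[cmp$direction == "down"]
  degenerate <- length(up) == 0 || length(down) == 0
  mean_up <- if (length(up)) mean(up) else NA_real_
  mean_down <- if (length(down)) mean(down) else NA_real_
  ratio <- if (!degenerate && mean_down > 0) mean_up / mean_down else NA_real_
  t_res <- if (!degenerate && length(up) >= 2 && length(down) >= 2 &&
               (sd(up) > 0 || sd(down) > 0)) {
    student_t(up, down)
  } else {
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }

  ## per-miRNA fraction of targets that are upregulated
  dir_of <- setNames(de$direction, de$transcript)
  mirna_tab <- net$edges |>
    dplyr::mutate(up = dir_of[.data$target] == "up") |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(degree = dplyr::n(), up_fraction = mean(.data$up)) |>
    dplyr::ungroup()
  ## degree-0 miRNAs have no defined fraction; they never pass the threshold
  qualifying <- mirna_tab[mirna_tab$degree > min_mirna_degree, , drop = FALSE]
  mean_up_fraction <- if (nrow(qualifying)) mean(qualifying$up_fraction)
                      else NA_real_

  coverage_n <- sum(target_deg$degree > 0)
  structure(
    list(target_degrees = target_deg,
         mirna_up_fractions = mirna_tab,
         mean_degree_up = mean_up,
         mean_degree_down = mean_down,
         ratio = ratio,
         t = t_res,
         degenerate = degenerate,
         min_mirna_degree = min_mirna_degree,
         include_zero_degree = include_zero_degree,
         mean_up_fraction = mean_up_fraction,
         n_qualifying_mirnas = nrow(qualifying),
         coverage_n = coverage_n,
         coverage_total = nrow(de),
         coverage_fraction = coverage_n / nrow(de)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  cat(sprintf("  mean degree up %.3f / down %.3f (ratio %.3f)\n",
              x$mean_degree_up, x$mean_degree_down, x$ratio))
  cat(sprintf("  Student's t = %.3f, df = %d, p = %.3g\n",
              x$t$statistic, as.integer(x$t$df), x$t$p_value))
  cat(sprintf("  coverage: %d / %d DE transcripts (%.1f%%)\n",
              x$coverage_n, x$coverage_total, 100 * x$coverage_fraction))
  cat(sprintf("  mean up-target fraction (miRNA degree > %d): %.1f%%\n",
              x$min_mirna_degree, 100 * x$mean_up_fraction))
  invisible(x)
}

#' Label-permutation test for the up/down mean-degree difference
#'
#' Nonparametric twin of the pooled t-test: up/down labels are shuffled over
#' transcripts (group sizes preserved) and the empirical p-value is
#' `(r + 1) / (n_perm + 1)`, where `r` counts permutations whose absolute
#' mean-degree difference is at least the observed one.
#'
#' @inheritParams enrichment_stats
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed for the permutation stream.
#' @return A one-row tibble with `observed_diff`, `p_value`, `n_perm`.
#' @examples
#' de <- tibble::tibble(transcript = paste0("g", 1:6), log2_fc = c(1, 1, 1, -1, -1, -1),
#'                      direction = rep(c("up", "down"), each = 3))
#' ints <- tibble::tibble(mirna = "m1", target = paste0("g", 1:3))
#' net <- build_bipartite(ints, de, "m1")
#' label_permutation_test(net, de, n_perm = 99, seed = 1)
#' @export
label_permutation_test <- function(net, de, n_perm = 999, seed = NULL,
                                   include_zero_degree = TRUE) {
  stopifnot(inherits(net, "bipartite_net"))
  validate_de_table(de, "de")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  deg_edge <- target_edge_degrees(net)
  degree <- as.integer(deg_edge[de$transcript])
  degree[is.na(degree)] <- 0L
  keep <- if (include_zero_degree) rep(TRUE, length(degree)) else degree > 0
  degree <- degree[keep]
  lab_up <- de$direction[keep] == "up"
  n_up <- sum(lab_up)
  if (n_up == 0 || n_up == length(lab_up))
    abort("both directions must be present for a permutation test.")
  observed <- mean(degree[lab_up]) - mean(degree[!lab_up])
  run <- function() {
    r <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(degree), n_up)
      diff_i <- mean(degree[idx]) - (sum(degree) - sum(degree[idx])) /
        (length(degree) - n_up)
      if (abs(diff_i) >= abs(observed)) r <- r + 1L
    }
    r
  }
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  tibble(observed_diff = observed,
         p_value = (r + 1) / (n_perm + 1),
         n_perm = as.integer(n_perm))
}
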