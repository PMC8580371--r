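## --- reading and writing the pipeline's standard tables ---

#' Read a Ct matrix from CSV
#'
#' First column `mirna`, header row of subject identifiers, numeric Ct
#' values. Validation failures (missing column, non-numeric or negative Ct,
#' duplicate ids) are reported with the offending names.
#'
#' @param path CSV file path.
#' @param compartment Optional compartment label (`"EV"`, `"intracellular"`)
#'   attached as an attribute.
#' @return A validated Ct tibble.
#' @export
read_ct_matrix <- function(path, compartment = NULL) {
  ct <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bad <- names(ct)[-1][!vapply(ct[-1], is.numeric, logical(1))]
  if (length(bad))
    abort(sprintf("non-numeric Ct column(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  validate_ct_matrix(ct, path)
  if (!is.null(compartment)) attr(ct, "compartment") <- compartment
  ct
}

#' Write a Ct or relative-expression matrix to CSV
#' @param x Matrix-shaped tibble (first column `mirna`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read a differential-expression table from CSV
#'
#' Columns `transcript`, `log2_fc`, `direction`; every direction label must
#' match the sign of its fold change (violations are reported with row
#' numbers).
#'
#' @param path CSV file path.
#' @return A validated DE tibble.
#' @export
read_de_table <- function(path) {
  de <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_de_table(de, path)
  de
}

#' Write a differential-expression table to CSV
#' @param de DE tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  validate_de_table(de)
  readr::write_csv(de, path)
  invisible(path)
}

#' Read a miRNA-target interaction table from TSV
#'
#' Columns `mirna`, `target`, optional `source` and `score`; records without
#' a score column (or with missing scores) are treated as unscored and pass
#' the top-percent filter unconditionally.
#'
#' @param path TSV file path.
#' @return A validated interaction tibble (always with a `score` column).
#' @export
read_interactions <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_interactions(x, path)
  if (!"source" %in% names(x)) x$source <- NA_character_
  if (!"score" %in% names(x)) x$score <- NA_real_
  x
}

#' Write a miRNA-target interaction table to TSV
#' @param interactions Interaction tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  validate_interactions(interactions)
  readr::write_tsv(interactions, path)
  invisible(path)
}

#' Read a PPI edge table from TSV
#'
#' Columns `protein_a`, `protein_b`, plus one numeric column per evidence
#' channel (e.g. `experiments`, `databases`).
#'
#' @param path TSV file path.
#' @return A PPI edge tibble.
#' @export
read_ppi_edges <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("protein_a", "protein_b") %in% names(x)))
    abort(sprintf("%s must have columns `protein_a` and `protein_b`.", path))
  x
}

#' Write a PPI edge table to TSV
#' @param edges PPI edge tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

network_edge_tibble <- function(net) {
  if (inherits(net, "bipartite_net")) {
    tibble(from = net$edges$mirna, to = net$edges$target)
  } else if (inherits(net, "ppi_net")) {
    net$edges
  } else {
    abort("`net` must be a bipartite_net or ppi_net.")
  }
}

#' Write a network as an edge-list TSV
#' @param net A `bipartite_net` or `ppi_net`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(network_edge_tibble(net), path)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' Bipartite networks carry a boolean `type` vertex attribute (miRNA side =
#' `FALSE`, target side = `TRUE`) following the usual bipartite convention.
#'
#' @param net A `bipartite_net` or `ppi_net`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  if (inherits(net, "bipartite_net")) {
    nodes <- c(net$mirnas, net$targets)
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
    g <- igraph::set_vertex_attr(g, "type",
                                 value = nodes %in% net$targets)
    if (nrow(net$edges))
      g <- igraph::add_edges(g, rbind(match(net$edges$mirna, nodes),
                                      match(net$edges$target, nodes)))
  } else if (inherits(net, "ppi_net")) {
    g <- as_ppi_igraph(net$nodes, net$edges)
  } else {
    abort("`net` must be a bipartite_net or ppi_net.")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write every simulated input table plus a JSON manifest
#'
#' Writes the two Ct matrices (CSV), the DE table (CSV), the interaction
#' table (TSV) and the PPI edge table (TSV) into `dir`, together with
#' `manifest.json` recording the generating configuration and seed.
#'
#' @param inputs Result of [simulate_inputs()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ct_ev = write_ct_matrix(inputs$ct_ev, file.path(dir, "ct_ev.csv")),
    ct_ic = write_ct_matrix(inputs$ct_ic, file.path(dir, "ct_ic.csv")),
    de = write_de_table(inputs$de, file.path(dir, "de_table.csv")),
    interactions = write_interactions(inputs$interactions,
                                      file.path(dir, "interactions.tsv")),
    ppi = write_ppi_edges(inputs$ppi, file.path(dir, "ppi_edges.tsv"))
  )
  manifest <- unclass(inputs$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}
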