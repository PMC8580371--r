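#' Simulate EV and intracellular qPCR Ct profiles
#'
#' Draws a miRNA-by-subject Ct matrix for each compartment. A fraction
#' `detect_fraction` of panel miRNAs is truly expressed: each expressed miRNA
#' gets a latent abundance per compartment, the two compartment vectors are
#' constructed to have *exactly* the sample Pearson correlation
#' `ev_ic_correlation` (on the latent, i.e. relative-expression, scale), and
#' observed Ct values are `ct_detect_mean - abundance + noise` (higher
#' abundance, lower Ct). Non-expressed miRNAs are recorded at the sentinel
#' `ct_floor_undetected` in every subject and compartment.
#'
#' @param config A [sim_config()].
#' @return A list with elements `ev` and `ic`, each a tibble whose first
#'   column is `mirna` followed by one numeric column per subject, with a
#'   `compartment` attribute.
#' @examples
#' prof <- simulate_ct_profiles(sim_config(n_mirnas_total = 50, seed = 1))
#' dim(prof$ev)
#' @export
simulate_ct_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_mirnas_total
  ns <- config$n_subjects
  mirnas <- sprintf("sim-miR-%04d", seq_len(n))
  subjects <- paste0("S", seq_len(ns))

  with_seed(stage_seed(config$seed, "ct_profiles"), {
    n_det <- round(config$detect_fraction * n)
    detected <- sort(sample(n, n_det))
    lat <- latent_abundance_pair(n_det, config$ct_detect_sd,
                                 config$ev_ic_correlation)
    make_ct <- function(latent, compartment) {
      m <- matrix(config$ct_floor_undetected, nrow = n, ncol = ns)
      if (n_det > 0) {
        noise <- matrix(rnorm(n_det * ns, 0, config$subject_sd), n_det, ns)
        m[detected, ] <- config$ct_detect_mean - latent + noise
      }
      out <- as_tibble(setNames(as.data.frame(m), subjects))
      out <- dplyr::bind_cols(tibble(mirna = mirnas), out)
      attr(out, "compartment") <- compartment
      out
    }
    list(ev = make_ct(lat$x, "EV"), ic = make_ct(lat$y, "intracellular"))
  })
}

## Latent abundance vectors for the two compartments with an exact planted
## sample correlation (orthogonalisation construction). |rho| = 1 short-cut
## keeps the zero-noise limit exactly proportional between compartments.
latent_abundance_pair <- function(n, sd_lat, rho) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  x <- rnorm(n, 0, sd_lat)
  if (n < 3 || abs(rho) == 1) return(list(x = x, y = rho * x))
  y0 <- rnorm(n)
  e <- residuals(lm(y0 ~ x))
  xs <- as.vector(scale(x))
  es <- as.vector(scale(e))
  y <- sd_lat * (rho * xs + sqrt(1 - rho^2) * es)
  list(x = x, y = y)
}

#' Simulate a differential-expression table
#'
#' Generates `n_up` transcripts with positive log2 fold change (direction
#' `"up"`) and `n_down` with negative log2 fold change (direction `"down"`),
#' with unique transcript identifiers.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `transcript`, `log2_fc`, `direction`.
#' @examples
#' de <- simulate_de_table(sim_config(seed = 1))
#' table(de$direction)
#' @export
simulate_de_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_up <- config$n_up
  n_down <- config$n_down
  with_seed(stage_seed(config$seed, "de_table"), {
    lfc <- c(runif(n_up, 0.5, 4), -runif(n_down, 0.5, 4))
    tibble(
      transcript = sprintf("GENE%04d", seq_len(n_up + n_down)),
      log2_fc = lfc,
      direction = ifelse(lfc > 0, "up", "down")
    )
  })
}

#' Simulate a miRNA-target interaction table
#'
#' Independent Bernoulli draw per (miRNA, transcript) pair: probability
#' `enrichment_ratio * p_base` for upregulated transcripts and `p_base` for
#' downregulated ones — the planted targeting enrichment the downstream
#' statistics are built to recover. Each interaction record carries a uniform
#' score in (0, 100] so the top-percent score filter can be exercised; the
#' score does not influence edge existence.
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param de_table A DE table as from [simulate_de_table()].
#' @param config A [sim_config()].
#' @return A tibble with columns `mirna`, `target`, `source`, `score`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' de <- simulate_de_table(cfg)
#' ints <- simulate_interactions(c("miR-a", "miR-b"), de, cfg)
#' @export
simulate_interactions <- function(mirna_ids, de_table, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_de_table(de_table)
  p_up <- config$p_base * config$enrichment_ratio
  if (p_up > 1) abort("p_base * enrichment_ratio exceeds 1; not a probability.")
  with_seed(stage_seed(config$seed, "interactions"), {
    pairs <- tidyr::expand_grid(mirna = mirna_ids,
                                target = de_table$transcript)
    p <- ifelse(de_table$direction[match(pairs$target, de_table$transcript)] == "up",
                p_up, config$p_base)
    keep <- rbinom(nrow(pairs), 1, p) == 1
    out <- pairs[keep, , drop = FALSE]
    out$source <- "synthetic"
    out$score <- runif(nrow(out)) * 100
    out
  })
}

#' Simulate a PPI edge table with planted hubs
#'
#' Generates a background protein network from a configurable model and adds
#' `n_planted_hubs` hub nodes, each wired to a random fraction (drawn from
#' `ppi_model$hub_frac`) of the background nodes. The default `"complexes"`
#' background partitions proteins into disjoint cliques emulating protein
#' complexes: within-complex edges are fully redundant, so shortest paths
#' between complexes run through the hubs and degree-preserving rewiring
#' (which destroys the complex structure) gives a contrastive null.
#' `"uniform"` (Erdos-Renyi) and `"attachment"` (preferential attachment)
#' backgrounds are available via [sim_config()].
#'
#' Every edge carries two evidence-channel scores (`experiments`,
#' `databases`) drawn uniformly in \[0, 1\]. If the background graph is
#' disconnected (expected for the complexes model) a note is attached as the
#' `"notes"` attribute rather than signalled as an error.
#'
#' Node identifiers reuse the DE-transcript namespace (`GENE...`), mirroring
#' a protein network reconstructed from the DE gene list; the planted hubs
#' occupy the last `n_planted_hubs` identifiers and are also returned as the
#' `"planted_hubs"` attribute.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `protein_a`, `protein_b`, `experiments`,
#'   `databases`; attributes `planted_hubs` (character) and possibly `notes`.
#' @examples
#' ppi <- simulate_ppi(sim_config(ppi_n_nodes = 24, n_planted_hubs = 1, seed = 1))
#' attr(ppi, "planted_hubs")
#' @export
simulate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_bg <- config$ppi_n_nodes
  n_hubs <- config$n_planted_hubs
  pm <- config$ppi_model
  model <- pm$model %||% "complexes"
  hub_frac <- pm$hub_frac %||% c(0.7, 0.9)

  with_seed(stage_seed(config$seed, "ppi"), {
    bg_edges <- switch(
      model,
      complexes = complexes_background(n_bg, pm$complex_size %||% 8),
      uniform = {
        g <- igraph::sample_gnp(n_bg, pm$p %||% 0.03)
        igraph::as_edgelist(g, names = FALSE)
      },
      attachment = {
        g <- igraph::sample_pa(n_bg, power = 1, m = pm$m %||% 3,
                               directed = FALSE)
        igraph::as_edgelist(g, names = FALSE)
      }
    )
    notes <- character(0)
    if (nrow(bg_edges) > 0) {
      g_bg <- igraph::graph_from_edgelist(bg_edges, directed = FALSE)
      g_bg <- igraph::add_vertices(g_bg, max(0, n_bg - igraph::vcount(g_bg)))
      if (igraph::components(g_bg)$no > 1)
        notes <- "background graph is disconnected before hub wiring"
    } else {
      notes <- "background graph has no edges before hub wiring"
    }

    hub_edges <- do.call(rbind, lapply(seq_len(n_hubs), function(h) {
      f <- runif(1, hub_frac[1], hub_frac[2])
      tgt <- sort(sample(n_bg, max(1, round(f * n_bg))))
      cbind(n_bg + h, tgt)
    }))
    el <- rbind(bg_edges, hub_edges)

    ## PPI nodes share the DE transcript namespace (the protein network is
    ## reconstructed from the DE gene list), so hubs can be cross-linked to
    ## the miRNA-target network
    ids <- sprintf("GENE%04d", seq_len(n_bg + n_hubs))
    out <- tibble(
      protein_a = ids[pmin(el[, 1], el[, 2])],
      protein_b = ids[pmax(el[, 1], el[, 2])],
      experiments = runif(nrow(el)),
      databases = runif(nrow(el))
    )
    attr(out, "planted_hubs") <- ids[n_bg + seq_len(n_hubs)]
    if (length(notes)) attr(out, "notes") <- notes
    out
  })
}

complexes_background <- function(n_bg, size) {
  starts <- seq(1, n_bg, by = size)
  el <- lapply(starts, function(s) {
    ids <- s:min(s + size - 1, n_bg)
    if (length(ids) < 2) return(NULL)
    t(combn(ids, 2))
  })
  out <- do.call(rbind, el)
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' Simulate every pipeline input at once
#'
#' Convenience wrapper drawing the Ct profiles, DE table, interaction table
#' and PPI edge table from one [sim_config()]. The miRNA identifiers used in
#' the interaction table are those detectable in the simulated EV profile, so
#' the tables compose like real study inputs.
#'
#' @param config A [sim_config()].
#' @param ct_max,min_count Detectability rule used to pick the miRNAs that
#'   enter the interaction simulation (defaults: Ct < 35 in at least
#'   ceiling(0.8 * n_subjects) subjects).
#' @return A list with elements `ct_ev`, `ct_ic`, `de`, `interactions`,
#'   `ppi`, and `config`.
#' @examples
#' inputs <- simulate_inputs(sim_config(n_mirnas_total = 100, seed = 2))
#' names(inputs)
#' @export
simulate_inputs <- function(config, ct_max = 35, min_count = NULL) {
  profiles <- simulate_ct_profiles(config)
  de <- simulate_de_table(config)
  det <- detect_mirnas(profiles$ev, ct_max = ct_max, min_count = min_count)
  detected_ids <- det$mirna[det$detected]
  interactions <- simulate_interactions(detected_ids, de, config)
  ppi <- simulate_ppi(config)
  list(ct_ev = profiles$ev, ct_ic = profiles$ic, de = de,
       interactions = interactions, ppi = ppi, config = config)
}
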