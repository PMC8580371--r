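#' Configuration for the synthetic-data generator
#'
#' Bundles every parameter of the synthetic study: the qPCR panel dimensions,
#' the latent-abundance model tying the EV and intracellular compartments
#' together, the differential-expression (DE) table sizes, the Bernoulli
#' miRNA-target model, and the planted-hub PPI background. One `sim_config`
#' (including its seed) fully determines every generated table, so a fixed
#' config reproduces the whole synthetic study byte for byte.
#'
#' Defaults mirror the study dimensions the pipeline is built around:
#' 752 profiled miRNAs of which ~8% (60) are detectable in 5 subjects,
#' an EV/intracellular correlation of 0.5 on the latent abundance scale,
#' 231 upregulated and 129 downregulated transcripts, and upregulated
#' transcripts targeted at twice the baseline rate.
#'
#' @param n_mirnas_total Number of miRNAs on the qPCR panel.
#' @param n_subjects Number of subjects (columns of each Ct matrix).
#' @param detect_fraction Fraction of panel miRNAs that are truly expressed.
#' @param ct_detect_mean Ct-scale location for expressed miRNAs; a miRNA with
#'   average latent abundance amplifies at this cycle.
#' @param ct_detect_sd Spread (SD, Ct units) of latent abundance across
#'   expressed miRNAs.
#' @param subject_sd Per-subject technical/biological noise SD (Ct units).
#' @param ct_floor_undetected Sentinel Ct recorded for non-amplifying wells
#'   (qPCR export convention; anything at or above `ct_max` is treated as
#'   undetected downstream).
#' @param ev_ic_correlation Planted Pearson correlation between compartments.
#'   Induced as an exact sample correlation of the latent abundance vectors,
#'   so downstream recovery measures pipeline attenuation, not bivariate
#'   sampling noise.
#' @param n_up,n_down Number of up- and downregulated DE transcripts.
#' @param p_base Baseline per-(miRNA, transcript) targeting probability for
#'   downregulated transcripts.
#' @param enrichment_ratio Multiplier: upregulated transcripts are targeted
#'   with probability `enrichment_ratio * p_base`.
#' @param ppi_n_nodes Number of background PPI nodes (excluding planted hubs).
#' @param ppi_model List of background-model settings: `model` one of
#'   `"complexes"` (disjoint cliques emulating protein complexes; default),
#'   `"uniform"` (Erdos-Renyi) or `"attachment"` (preferential attachment);
#'   `complex_size` clique size for `"complexes"`; `p` edge probability for
#'   `"uniform"`; `m` edges per new node for `"attachment"`;
#'   `hub_frac` length-2 range for the fraction of background nodes each
#'   planted hub is wired to.
#' @param n_planted_hubs Number of planted hub nodes.
#' @param seed Integer seed determining every generated artifact.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_up
#' @export
sim_config <- function(n_mirnas_total = 752,
                       n_subjects = 5,
                       detect_fraction = 0.08,
                       ct_detect_mean = 28,
                       ct_detect_sd = 2,
                       subject_sd = 0.8,
                       ct_floor_undetected = 40,
                       ev_ic_correlation = 0.5,
                       n_up = 231,
                       n_down = 129,
                       p_base = 0.05,
                       enrichment_ratio = 2,
                       ppi_n_nodes = 120,
                       ppi_model = list(model = "complexes", complex_size = 8,
                                        p = 0.03, m = 3,
                                        hub_frac = c(0.7, 0.9)),
                       n_planted_hubs = 3,
                       seed = 1L) {
  num_fields <- list(
    n_mirnas_total = n_mirnas_total, n_subjects = n_subjects,
    detect_fraction = detect_fraction, ct_detect_mean = ct_detect_mean,
    ct_detect_sd = ct_detect_sd, subject_sd = subject_sd,
    ct_floor_undetected = ct_floor_undetected,
    ev_ic_correlation = ev_ic_correlation, n_up = n_up, n_down = n_down,
    p_base = p_base, enrichment_ratio = enrichment_ratio,
    ppi_n_nodes = ppi_n_nodes, n_planted_hubs = n_planted_hubs, seed = seed
  )
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number (got %s).",
                    nm, paste(format(v), collapse = ", ")))
    }
  }
  if (detect_fraction < 0 || detect_fraction > 1)
    abort("`detect_fraction` must be in [0, 1].")
  if (p_base < 0 || p_base > 1) abort("`p_base` must be in [0, 1].")
  if (abs(ev_ic_correlation) > 1)
    abort("`ev_ic_correlation` must be in [-1, 1].")
  if (p_base * enrichment_ratio > 1)
    abort(sprintf("p_base * enrichment_ratio = %.3f exceeds 1; not a probability.",
                  p_base * enrichment_ratio))
  if (n_up < 1 || n_down < 1) abort("`n_up` and `n_down` must be >= 1.")
  if (n_mirnas_total < 1 || n_subjects < 1)
    abort("`n_mirnas_total` and `n_subjects` must be >= 1.")
  if (ppi_n_nodes < n_planted_hubs + 2)
    abort("`ppi_n_nodes` must be at least `n_planted_hubs` + 2.")
  model <- ppi_model$model %||% "complexes"
  if (!model %in% c("complexes", "uniform", "attachment"))
    abort("`ppi_model$model` must be one of \"complexes\", \"uniform\", \"attachment\".")

  structure(c(num_fields, list(ppi_model = ppi_model)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  panel: %d miRNAs x %d subjects, detect_fraction %.3f\n",
              x$n_mirnas_total, x$n_subjects, x$detect_fraction))
  cat(sprintf("  Ct model: mean %.1f, latent sd %.1f, subject sd %.1f, floor %.1f\n",
              x$ct_detect_mean, x$ct_detect_sd, x$subject_sd,
              x$ct_floor_undetected))
  cat(sprintf("  EV/IC correlation: %.2f\n", x$ev_ic_correlation))
  cat(sprintf("  DE: %d up / %d down; targeting p_base %.3f, ratio %.2f\n",
              x$n_up, x$n_down, x$p_base, x$enrichment_ratio))
  cat(sprintf("  PPI: %d background nodes (%s), %d planted hubs; seed %d\n",
              x$ppi_n_nodes, x$ppi_model$model %||% "complexes",
              x$n_planted_hubs, as.integer(x$seed)))
  invisible(x)
}
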