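---
title: "EV-miRNA cargo profiling and miRNA-target network topology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EV-miRNA cargo profiling and miRNA-target network topology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmirnet)
```

## The analysis

Conventional CD4+ T cells (Tconv) stimulated through the T-cell receptor
release extracellular vesicles (EVs) whose microRNA cargo can be profiled by
qPCR. `evmirnet` implements the downstream computational analysis of such a
study as a reusable, tested pipeline:

1. **Profiling** — call a miRNA *detectable* when its Ct is strictly below a
   threshold in enough subjects, normalize detectable miRNAs by the
   per-sample global mean, rank them, and correlate EV with intracellular
   abundance.
2. **Target network** — restrict a validated miRNA-target interaction table
   to transcripts differentially expressed (DE) on stimulation, build the
   bipartite miRNA-target graph, and ask whether upregulated transcripts
   are targeted more heavily than downregulated ones (pooled *t*-test and a
   label-permutation twin).
3. **PPI topology** — filter a protein-protein interaction (PPI) table by
   evidence-channel scores, compute betweenness, bridging and centroid
   centralities, and call consensus hubs.
4. **Null models** — judge topological values against degree-preserving
   randomized networks.

Every stage can be exercised end to end on synthetic data with planted
ground truth, which is what the test suite does.

## Profiling model and conventions

Ct is the qPCR cycle threshold; lower Ct means higher abundance. The
default detectability rule is **Ct < 35 in at least ceiling(0.8 × subjects)
subjects** (4 of 5 at the default study size). The inequality is strict: a
well at exactly 35.0 does not count.

Global-mean normalization computes, per subject, the mean Ct over the
*detected panel*, restricted to wells that amplified (Ct < 35) in that
subject; relative expression is `global_mean − Ct`, so positive values mean
more abundant than the panel average and present values sum to zero within
each subject. Two decisions here were genuinely open:

* the global mean could have been taken over all amplifying wells rather
  than the detected panel; we use the detected panel (an "internal miRNA
  global mean" is naturally the panel that survived detection) and the
  threshold is a visible argument (`ct_max`), so the alternative is one
  call away;
* undetected wells are encoded as a sentinel Ct of 40 in generated data
  (qPCR export convention) but any value at or above `ct_max` is treated as
  undetected, so a missing-value encoding works identically.

The EV/intracellular correlation is the Pearson correlation of *per-miRNA
mean relative expression* across the intersection of the two compartments'
detected sets — one point per miRNA, matching how a single R value for a
panel is usually reported — and the size of that intersection is returned
with the estimate.

## The bipartite network and enrichment statistics

Interaction records are optionally thinned per source database to the top
20% of scores (descending rank, all records tied at the boundary score
kept; unscored records always pass — they represent validated entries
without a prediction score). Records are then restricted to DE transcripts
— the network keeps *only* targets on the DE list — and duplicate
(miRNA, target) records across sources collapse to one edge (union
semantics; the sources agree on the pair, so intersection would only
discard evidence).

Enrichment is computed on the network built over both DE directions:

* per-transcript degree = number of distinct miRNAs targeting it;
  transcripts with no edge count as degree 0 by default (`degree
  distribution of up- and downregulated transcripts` names the transcript
  sets, not the edge-bearing subset) — a switch restricts to edge-bearing
  transcripts;
* group means, their ratio, and a classical pooled two-sample *t*-test
  (df = n_up + n_down − 2);
* per-miRNA fraction of targets that are upregulated, averaged over miRNAs
  with degree strictly greater than 2 ("more than 2 targets" read
  strictly);
* coverage: the count and fraction of DE transcripts with at least one
  edge.

A label-permutation test shuffles the up/down labels over transcripts
(group sizes preserved) and reports `(r + 1)/(n_perm + 1)` for the absolute
mean-degree difference — a nonparametric companion whose calibration under
no planted enrichment is part of the acceptance checks.

## Centralities and hub selection

All three centralities follow the conventions of the Cytoscape-style
centrality tooling this analysis emulates:

* **Betweenness** `C_B(v) = Σ_{s<t} σ_st(v)/σ_st`, unordered pairs counted
  once, endpoints excluded, no normalization; computed by Brandes'
  single-source dependency accumulation in compiled code, and required by
  the tests to equal exhaustive path enumeration on small graphs.
* **Bridging coefficient** `BCoef(v) = (1/deg v) / Σ_{u∈N(v)} 1/deg(u)`,
  and **bridging centrality** `BrC(v) = C_B(v) × BCoef(v)`; isolated nodes
  get coefficient 0 with a log notice.
* **Centroid** `C_cen(v) = min_{w≠v} (γ_v(w) − γ_w(v))` with `γ_v(w)` the
  number of nodes strictly closer to v than to w, both v and w excluded
  from the counted universe (definitional variants exist; this one is
  pinned by the brute-force oracle in the tests). Distances come from
  breadth-first shortest paths; betweenness and centroid are computed per
  connected component, singleton components scoring 0.

A node is a **hub** when its value strictly exceeds the network-wide mean.
The consensus rule (`mode = "all"`) requires this simultaneously for
betweenness, bridging and centroid — the conservative reading when three
centralities are listed alongside a single above-average rule — and
`mode = "any"` gives the permissive alternative. Network means are taken
over all nodes, including every component.

PPI edges pass the evidence filter when they strictly exceed the threshold
in *at least one* configured channel (defaults: experiments > 0.0031,
databases > 0.36). The phrasing "Experiments and Databases annotated
interactions" is ambiguous between union and intersection; union is the
default because it retains any interaction with qualifying evidence of
either kind, and `mode = "all"` provides the intersection.

## Randomized-network nulls

The null model is the degree-preserving double-edge swap: edges (a,b) and
(c,d) become (a,d) and (c,b) when no self-loop or duplicate results (and,
for bipartite networks, sides are preserved by construction). Defaults:
`10 × |E|` swap *attempts* — failed attempts count, making runtime
predictable and the (network, n_swaps, seed) triple fully reproducible.
Empirical p-values use `(r + 1)/(n + 1)`; the two-sided version doubles the
smaller tail (capped at 1). An Erdős–Rényi same-density alternative is
deliberately not provided as a default: degree preservation is the standard
conditioning for centrality significance, and the exact randomization depth
and replicate count are configurable (`n_swaps`, `n_random`) because no
canonical values exist.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its seed determines every
generated table exactly.

| Parameter | Default | Meaning |
|---|---|---|
| `n_mirnas_total` | 752 | qPCR panel size |
| `n_subjects` | 5 | donors |
| `detect_fraction` | 0.08 | truly expressed miRNAs (60/752) |
| `ct_detect_mean` | 28 | Ct at average latent abundance |
| `ct_detect_sd` | 2.0 | latent abundance spread (Ct units) |
| `subject_sd` | 0.8 | per-subject noise (Ct units) |
| `ct_floor_undetected` | 40 | sentinel for non-amplifying wells |
| `ev_ic_correlation` | 0.5 | planted EV/IC correlation |
| `n_up`, `n_down` | 231 / 129 | DE table composition |
| `p_base` | 0.05 | per-pair targeting probability, down |
| `enrichment_ratio` | 2 | `p_up = 2 × p_base` |
| `ppi_n_nodes` | 120 | PPI background nodes |
| `n_planted_hubs` | 3 | hub nodes added to the background |

The latent-abundance spread of 2 Ct units reproduces a ranked
relative-expression range of roughly +4 to −3, the magnitude seen in real
ranked EV-miRNA panels, and 0.8 Ct of subject noise is a typical
biological-replicate spread for qPCR.

Three generator choices deserve explanation:

* **The EV/IC correlation is planted as an exact sample correlation** of
  the latent abundance vectors (orthogonalisation construction), not as a
  population parameter of a bivariate normal. The generator's role is to
  plant ground truth: with an exact plant, the downstream estimate measures
  what the pipeline adds (subject noise, detection censoring, global-mean
  normalization) rather than the irreducible sampling noise of a 60-point
  bivariate draw, which at ρ = 0.5 has a standard deviation of about 0.10
  and would dominate any recovery assessment.
* **The PPI background is a "complexes" model**: disjoint cliques of 8
  emulating protein complexes, with each planted hub wired to a random
  70–90% of background nodes. Clustering into complexes is the signature
  feature of real PPI networks, and it is exactly what degree-preserving
  rewiring destroys — giving the null model genuine contrast. It also
  makes the consensus hub rule meaningful: bridging centrality *penalises*
  degree, so hubs are only recoverable when inter-complex shortest paths
  run through them; in an unstructured Erdős–Rényi or preferential
  attachment background (both available via `ppi_model`), ordinary nodes
  retain enough betweenness and bridging that no wiring density makes the
  planted hubs pass all three above-mean tests. PPI node identifiers reuse
  the DE transcript namespace, as a protein network reconstructed from a
  DE gene list would.
* **Interaction scores are uniform on (0, 100] and independent of edge
  existence** — they exist to exercise the top-percent filter, nothing
  else. Applying the default 20% filter therefore thins the synthetic
  network uniformly: coverage drops accordingly while the planted degree
  *ratio* is preserved in expectation.

What the generator does **not** emulate: amplification efficiency and
plate effects, miRNA-family correlated expression, database-specific
biases of target evidence, and PPI evidence scores correlated with
topology. Passing tests therefore demonstrate the statistical machinery
recovers planted structure under idealised sampling — not that any real
dataset satisfies these models.

## Numerical choices and degenerate inputs

* Ties are broken lexicographically everywhere a ranking is reported, so
  outputs are deterministic.
* If one DE direction is empty (or absent from the comparison), the
  enrichment ratio and *t*-test are flagged undefined rather than erroring;
  an empty interaction table yields a valid network with degree-0 miRNAs
  and coverage 0.
* The pooled *t*-test refuses zero pooled variance; the correlation refuses
  fewer than 3 shared miRNAs or a zero-variance compartment.
* Networks with fewer than 2 edges are returned unchanged from rewiring
  with a warning; a triangle, which admits no valid swap, comes back
  identical with 0 accepted swaps.
* One run seed drives everything: per-stage seeds are derived by a stable
  hash of (seed, stage label), so any stage can be re-run in isolation and
  a repeated run writes a byte-identical summary JSON.

## Problem sizes used by the tests

The acceptance-style checks run at the study scale they assert: 200 random
graphs (≤ 7 nodes) against brute-force centrality oracles; 400 replicate
studies at 60 miRNAs × 360 transcripts for enrichment recovery (the
per-seed success probability of the ratio window is ≈ 0.92, close enough
to the asserted 90% bound that a smaller replicate count would let binomial
noise decide the verdict); 200 null-calibration studies with 199
permutations each; 100 synthetic PPI draws for hub recovery plus 50 draws
× 50 rewired replicates for the betweenness null; 200 seeds for
correlation recovery. The full suite completes in a few minutes on one
core.

## Limitations

* Identifiers are opaque, case-sensitive strings: no gene-symbol aliasing
  or cross-database id mapping is attempted.
* The top-percent filter models the retrieval tool's score cutoff, not the
  underlying prediction algorithms; no seed-match or 3′UTR analysis is
  included.
* Degree-preserving rewiring samples the fixed-degree graph space by
  Markov chain, with mixing asserted only empirically (`10 × |E|`
  attempts); exact uniform sampling is out of scope.
* The pipeline quantifies association between EV-miRNA cargo and
  activation-induced transcripts; it makes no claim about suppression in
  recipient cells.
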