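# evmirnet

Analysis pipeline for the microRNA cargo of extracellular vesicles (EVs)
released by TCR-stimulated conventional CD4+ T cells (Tconv), for
systems-biology researchers asking two questions of such data:

1. Do the miRNAs a T cell exports in EVs preferentially target the
   transcripts it upregulates on activation?
2. Are the most heavily targeted transcripts hubs of the protein–protein
   interaction (PPI) network?

The package takes four tabular inputs — qPCR Ct matrices (miRNA × subject,
one per compartment), a differential-expression (DE) table, a miRNA–target
interaction table, and a PPI edge table with evidence-channel scores — and
provides a synthetic-data module that generates all of them with planted
ground truth, so the whole pipeline is testable without access to any
study's raw data.

## What it computes

**Profiling.** A miRNA is detectable when Ct < 35 in at least 4 of 5
subjects (strict inequality; both knobs configurable). Detected miRNAs are
normalized by the per-sample global mean, `rel(m, s) = mean_s(Ct) − Ct(m, s)`,
so values are log2-scale, sum to zero within a subject, and larger means
more abundant. EV and intracellular profiles are compared by the Pearson
correlation of per-miRNA mean relative expression over the shared detected
set.

**Target network.** Interactions are optionally thinned to the top 20% of
scores per source (boundary ties kept, unscored records always kept),
restricted to DE transcripts, and de-duplicated into a bipartite graph. A
transcript's degree is the number of distinct miRNAs targeting it. The
up- versus downregulated degree distributions are compared by a pooled
two-sample *t*-test and by a label-permutation test with
`p = (r + 1)/(n_perm + 1)`.

**PPI topology.** Edges pass when they strictly exceed the evidence
threshold in at least one channel (experiments > 0.0031,
databases > 0.36). Three node centralities are computed:

- betweenness `C_B(v) = Σ_{s<t} σ_st(v)/σ_st` (Brandes, unnormalized);
- bridging `BrC(v) = C_B(v) · BCoef(v)` with
  `BCoef(v) = (1/deg v) / Σ_{u∈N(v)} 1/deg(u)`;
- centroid `C_cen(v) = min_{w≠v} (γ_v(w) − γ_w(v))`, where `γ_v(w)` counts
  nodes strictly closer to v than to w.

A node is a consensus hub when it strictly exceeds the network mean in all
three. Hub significance is judged against degree-preserving double-edge-swap
randomizations via empirical p-values.

## Worked example

A full simulated study at the default scale (752-miRNA panel, 5 subjects,
231 up / 129 down DE transcripts, planted 2× targeting enrichment, PPI
with 3 planted hubs):

```r
library(evmirnet)

cfg <- run_config(simulate = sim_config(), seed = 1)
res <- run_pipeline(cfg)

res$net_both
#> <bipartite_net> 60 miRNAs, 225 targets (both), 369 edges

res$enrichment
#> <enrichment_result>
#>   mean degree up 1.208 / down 0.698 (ratio 1.731)
#>   Student's t = 4.620, df = 358, p = 5.36e-06
#>   coverage: 225 / 360 DE transcripts (62.5%)
#>   mean up-target fraction (miRNA degree > 2): 75.3%

res$correlation
#> # A tibble: 1 × 2
#>   estimate     n
#>      <dbl> <int>
#> 1    0.465    60
```

60 of 752 miRNAs pass detection (the planted 8%), the EV/intracellular
correlation recovers the planted 0.5 up to noise, and upregulated
transcripts carry ~1.7× the miRNA-target degree of downregulated ones —
the planted 2× attenuated only by sampling noise after the top-20% score
filter thins the network (the ratio is preserved in expectation; coverage
is not). The consensus hub selection recovers all three planted hubs, each
far above the rewiring null:

```r
tibble::as_tibble(res$hubs)[, c("node", "degree", "betweenness", "bridging",
                                "centroid", "mirna_targeting")]
#> # A tibble: 3 × 6
#>   node     degree betweenness bridging centroid mirna_targeting
#>   <chr>     <int>       <dbl>    <dbl>    <dbl>           <int>
#> 1 GENE0121    102       2501.     2.29        5               2
#> 2 GENE0122     89       1870.     2.26      -13               0
#> 3 GENE0123     97       2349.     2.37       -5               0

glance(res$nulls)$min_p_upper
#> [1] 0.00990099
```

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` visualisations (degree box plots, null violins,
centrality landscapes). With `out_dir` set, `run_pipeline()` writes every
stage table (CSV/TSV), both networks as edge lists and GraphML, a
`summary.json`, and a run log; a fixed seed reproduces `summary.json` byte
for byte.

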