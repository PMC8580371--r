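Package: evmirnet
Title: EV-miRNA Cargo Profiling and miRNA-Target Network Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the microRNA cargo of extracellular
    vesicles (EVs) released by TCR-stimulated conventional CD4+ T cells.
    Implements detectability filtering and global-mean normalization of
    qPCR Ct profiles, EV versus intracellular correlation, construction of
    the bipartite network between EV-miRNAs and differentially expressed
    transcripts with target-set enrichment statistics, protein-protein
    interaction (PPI) edge filtering by evidence-channel scores,
    betweenness, bridging and centroid centralities with consensus hub
    selection, and degree-preserving randomized-network null models. A
    synthetic-data module generates all pipeline inputs with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
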