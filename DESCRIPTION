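Package: consurvey
Title: Evolutionary Conservation Comparison of Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compares the evolutionary conservation of two gene sets (for
    example FDA-approved drug targets against family-excluded non-targets)
    across a panel of species and a human protein-protein interaction
    network. Computes per-species dN/dS evolutionary rates from one-to-one
    ortholog tables, protein conservation scores by Smith-Waterman local
    alignment under BLOSUM62 with affine gaps, ortholog percentages, and
    four node-topology metrics (degree, clustering coefficient, Brandes
    betweenness centrality, average shortest path length), then contrasts
    the sets with per-species Wilcoxon rank-sum tests and a cross-species
    Wilcoxon signed-rank test on the per-species medians (exact and
    normal-approximation modes). A seeded synthetic-study generator with
    configurable planted group effects emulates the ortholog, sequence,
    family and interaction inputs so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
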