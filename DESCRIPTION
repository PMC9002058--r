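Package: gutbrainnet
Title: Gut Microbiota, Brain Network Topology and Cognition Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how gut microbial diversity and enterotypes
    relate to human brain network organization and cognition. Builds binary
    structural connectomes from fiber-number matrices and functional
    connectomes from regional BOLD time series across a sparsity sweep,
    computes global and nodal graph-theoretical metrics with small-world
    normalization against degree-preserving random networks and AUC
    summaries, quantifies per-region structure-function coupling, derives
    alpha diversity and Jensen-Shannon/PAM enterotypes from taxon count
    tables, and runs the multi-stage inferential chain: covariate-adjusted
    partial correlations with FDR control, enterotype ANOVA with Bonferroni
    post hoc tests, and percentile-bootstrap mediation analysis. A synthetic
    cohort generator with planted effect structure makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    cluster,
    vegan,
    pracma,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
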