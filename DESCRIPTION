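Package: phylosieve
Title: Gene-Level Diagnostics, Filtering and Signal Dissection for
    Phylogenomic Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting phylogenomic signal at the gene level in
    amino-acid supermatrices. Implements per-gene diagnostics (saturation as
    one minus the slope of p-distances on patristic distances, root-to-tip
    variance, relative composition frequency variability, missing data),
    rank-based gene exclusion with random-subsampling replicates, a small
    phylogenetic likelihood engine (Felsenstein pruning under reversible
    amino-acid models with discrete-gamma and invariant sites), gene-wise
    delta log-likelihood dissection of topological signal with a confounder
    screen (multiple regression and a permutation test on Wilks' lambda),
    the SOWH parametric-bootstrap topology test, quartet-based species-tree
    estimation with gene subsampling experiments, posterior root-to-tip rate
    summaries, contamination screens (alien index, cross-sample p-distance
    residuals, gene-tree diameter outliers), and a synthetic-data generator
    with lineage-specific rates, coalescent gene-tree discordance,
    compositional bias, occupancy masking and planted contaminants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
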