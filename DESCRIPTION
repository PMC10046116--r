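Package: gxn
Title: Generalizable Gene Self-Expressive Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sparse gene regulatory networks from expression matrices by
    training, for every gene, a constrained linear self-expression model over a
    set of candidate regulators.  Two solvers are provided, orthogonal matching
    pursuit with an l0 budget and elastic net with a pathwise alpha grid, both
    tuned by nested cross-validation so that every retained model carries an
    honest out-of-sample R2 estimate.  Downstream tools cover network topology
    summaries, AUROC/AUPR scoring against gold-standard edge lists, greedy
    community detection under a resolution-scaled directed modularity with
    automatic elbow-based resolution selection, community-level gene set
    enrichment against sample classes, and GO-style over-representation tests.
    A synthetic-data generator produces union-of-subspaces expression fixtures
    with planted sparse regulatory structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    glmnet,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
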