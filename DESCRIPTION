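Package: prednet
Title: Predictive Networks for Confounder Screening in Categorical Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies potential confounders in high-dimensional categorical
    survey data by building a predictive network: every one-hot dummy
    variable is predicted by a gradient-boosted tree ensemble using all
    dummies from other variables, per-target gain importances become the
    edges of a directed weighted graph, and variables are ranked by HITS hub
    centrality (the principal eigenvector of A A'). Includes train/test AUC
    evaluation per target, stratified replication with cross-stratum Pearson
    agreement of hub scores, a synthetic survey generator with planted
    confounders for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
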