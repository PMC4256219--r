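Package: gofunsim
Title: Information-Content-Based Gene Ontology Functional Similarity Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes protein functional similarity from Gene Ontology (GO)
    annotations using the full family of information-content (IC) based
    measures: four term-IC models (annotation frequency, Zhang descendant
    count, Wang S-values, GO-universal topology), the node-based term
    semantic similarity models built on them (Resnik, Lin, Nunivers,
    Relevance, Li, their XGraSM enhancements and Wang's hybrid formula),
    and eight protein-level measures (Avg, Max, ABM, BMA, SimGIC, SimDIC,
    SimUIC, SimUI) combined into a 57-measure grid. Includes OBO 1.2 and
    GAF 2.x readers, true-path annotation propagation, evaluation protocols
    (ROC/AUC for protein-protein interaction coherence, entropy/mutual
    information/Rand index for clustering power, Pearson correlation
    against reference similarities) and generators for synthetic
    ontologies, annotation corpora, planted protein-pair sets and
    planted-community co-expression graphs.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
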