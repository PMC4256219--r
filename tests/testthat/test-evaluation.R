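# Evaluation statistics: negative sampling, ROC/AUC, correlation, Louvain
# clustering and partition comparison.

test_that("negative sampling is uniform over allowed pairs and reproducible", {
  prots <- c("a", "b", "c", "d")
  s1 <- sample_negatives(prots, 3, NULL, seed = 11)
  s2 <- sample_negatives(prots, 3, NULL, seed = 11)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 3)
  expect_true(all(s1$protein_a != s1$protein_b))
  expect_equal(anyDuplicated(paste(s1$protein_a, s1$protein_b)), 0)
  # forbidding all 6 pairs leaves nothing to draw
  all6 <- as.data.frame(t(combn(prots, 2)))
  names(all6) <- c("protein_a", "protein_b")
  expect_error(sample_negatives(prots, 1, all6, seed = 1), "only 0")
  # forbidden pairs are never drawn
  forb <- data.frame(protein_a = "a", protein_b = "b")
  for (seed in 1:20) {
    s <- sample_negatives(prots, 5, forb, seed = seed)
    expect_false(any(pmin(s$protein_a, s$protein_b) == "a" &
                       pmax(s$protein_a, s$protein_b) == "b"))
  }
})

test_that("AUC matches hand-enumerated and brute-force values", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.4), c(0.5, 0.1))$auc, 0.75)
  expect_equal(roc_auc(0.5, 0.5)$auc, 0.5)
  expect_error(roc_auc(c(0.5, NA), 0.2), "finite")
  expect_error(roc_auc(numeric(0), 0.2), "nonempty")
  withr::with_seed(3, {
    for (i in 1:100) {
      pos <- round(runif(sample(2:20, 1)), 2)  # rounding forces ties
      neg <- round(runif(sample(2:20, 1)), 2)
      expect_equal(roc_auc(pos, neg)$auc, oracle_auc(pos, neg))
      # complement identity
      expect_equal(roc_auc(pos, neg)$auc + roc_auc(neg, pos)$auc, 1)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(9, {
    pos <- runif(40)
    neg <- runif(35, max = 0.8)
  })
  ours <- roc_auc(pos, neg)$auc
  ref <- suppressMessages(pROC::auc(
    response = c(rep(1, 40), rep(0, 35)),
    predictor = c(pos, neg),
    levels = c(0, 1), direction = "<"
  ))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("ROC points span (0,0) to (1,1) and tidy/glance/autoplot work", {
  r <- roc_auc(c(0.9, 0.4), c(0.5, 0.1))
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_identical(tidy(r), r$roc)
  expect_equal(glance(r)$auc, 0.75)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("pearson matches hand covariance and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2)), 0.5)
  expect_error(pearson(x, c(1, 1, 1)), "zero-variance")
  expect_error(pearson(x, c(1, 2)), "equal length")
})

test_that("Louvain clustering recovers two cliques and handles edge cases", {
  clique_edges <- function(nodes) {
    p <- combn(nodes, 2)
    tibble::tibble(protein_a = p[1, ], protein_b = p[2, ], weight = 1)
  }
  edges <- dplyr::bind_rows(
    clique_edges(paste0("x", 1:4)),
    clique_edges(paste0("y", 1:4)),
    tibble::tibble(protein_a = "x1", protein_b = "y1", weight = 0.1)
  )
  part <- cluster_graph(edges, seed = 5)
  memb <- setNames(part$cluster, part$node)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("x", 1:4)])), 1)
  expect_equal(length(unique(memb[paste0("y", 1:4)])), 1)
  # single edge: one cluster; edgeless nodes: singletons
  single <- cluster_graph(tibble::tibble(protein_a = "a", protein_b = "b"),
                          seed = 1)
  expect_equal(length(unique(single$cluster)), 1)
  lonely <- cluster_graph(tibble::tibble(protein_a = character(),
                                         protein_b = character(),
                                         weight = numeric()),
                          seed = 1, nodes = c("u", "v", "w"))
  expect_equal(length(unique(lonely$cluster)), 3)
  expect_error(cluster_graph(tibble::tibble(protein_a = character(),
                                            protein_b = character()),
                             seed = 1), "empty")
})

test_that("partition comparison reproduces the 2x2 hand enumeration", {
  nodes <- paste0("p", 1:4)
  g <- setNames(c(1, 1, 2, 2), nodes)
  same <- compare_partitions(g, g)
  expect_equal(same$nmi, 1)
  expect_equal(same$rand_index, 1)
  crossed <- compare_partitions(g, setNames(c(1, 2, 1, 2), nodes))
  expect_equal(crossed$mi, 0)
  expect_equal(crossed$nmi, 0)
  expect_equal(crossed$rand_index, 2 / 6)
  relabeled <- compare_partitions(g, setNames(c(9, 9, 4, 4), nodes))
  expect_equal(relabeled$nmi, 1)
  expect_equal(relabeled$rand_index, 1)
  expect_error(compare_partitions(g, setNames(c(1, 2), c("p1", "zz"))),
               "universe")
})

test_that("partition comparison invariants hold on random partitions", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      nodes <- paste0("n", 1:n)
      g <- setNames(sample(1:4, n, replace = TRUE), nodes)
      c_ <- setNames(sample(1:3, n, replace = TRUE), nodes)
      cmp <- compare_partitions(g, c_)
      expect_true(cmp$nmi >= -1e-12 && cmp$nmi <= 1 + 1e-12)
      expect_true(cmp$rand_index >= 0 && cmp$rand_index <= 1)
      # contingency margins reproduce cluster sizes
      expect_equal(unname(rowSums(cmp$contingency)),
                   unname(as.vector(table(g))))
      expect_equal(unname(colSums(cmp$contingency)),
                   unname(as.vector(table(c_))))
      # label permutation invariance
      perm <- setNames(sample(10:13), 1:4)[as.character(g)]
      names(perm) <- nodes
      expect_equal(compare_partitions(perm, c_)$nmi, cmp$nmi)
      # sqrt normalisation stays within [0,1] too
      sq <- compare_partitions(g, c_, nmi_norm = "sqrt")
      expect_true(sq$nmi >= -1e-12 && sq$nmi <= 1 + 1e-12)
    }
  })
})

test_that("eval_ppi scores every config and errors on unannotated positives", {
  inst <- random_instance(31, n_terms = 25, n_proteins = 30)
  spec <- synth_spec(n_terms = 25, n_proteins = 30, n_pairs = 10, seed = 31)
  pp <- planted_ppi(inst$ann, spec)
  configs <- enumerate_measures()[c(1, 33, 45, 57), ]
  res <- eval_ppi(pp$positives, inst$ann, inst$dag, configs, seed = 8)
  expect_equal(nrow(res), 4)
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  bad <- tibble::tibble(protein_a = "ghost", protein_b = "P00001")
  expect_error(eval_ppi(bad, inst$ann, inst$dag, configs, seed = 1),
               "unannotated")
})

test_that("re-weighting with the original weights reproduces the ground truth", {
  cx <- planted_coexpression(synth_spec(n_terms = 30, community_size = 10,
                                        seed = 17))
  truth <- cluster_graph(cx$edges, seed = 4)
  again <- cluster_graph(cx$edges, seed = 4, nodes = truth$node)
  cmp <- compare_partitions(truth, again)
  expect_equal(cmp$nmi, 1)
  expect_equal(cmp$rand_index, 1)
})

test_that("eval_clustering returns one NMI/RI row per config", {
  cx <- planted_coexpression(synth_spec(n_terms = 30, community_size = 8,
                                        mean_terms = 1, seed = 23))
  configs <- enumerate_measures()[enumerate_measures()$label %in%
                                    c("AGIC", "SimUI", "UBMA"), ]
  res <- eval_clustering(cx$edges, cx$ann, cx$dag, configs, seed = 6)
  expect_equal(sort(res$label), c("AGIC", "SimUI", "UBMA"))
  expect_true(all(res$nmi >= -1e-12 & res$nmi <= 1 + 1e-12))
  expect_true(all(res$rand_index >= 0 & res$rand_index <= 1))
  expect_s3_class(plot_measure_eval(res), "ggplot")
})
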