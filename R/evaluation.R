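# Evaluation protocols.
#
# Three ways of asking whether a functional similarity measure captures
# biology:
#  * ROC/AUC over a positive (interacting) vs negative (random annotated)
#    protein-pair set — AUC is the rank statistic (probability a positive
#    outscores a negative, ties counted half);
#  * Pearson correlation against reference similarity vectors;
#  * clustering power: re-weight a co-expression graph with a measure,
#    re-cluster (Louvain), and compare against the ground-truth partition
#    via entropy/mutual information/NMI and the Rand index.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Sample random negative protein pairs
#'
#' Uniformly samples `n` distinct unordered pairs of annotated proteins,
#' excluding self-pairs and a forbidden (positive) pair set. Mirrors the
#' construction of a negative set the same size as the positives, drawn at
#' random from annotated protein pairs.
#'
#' @param proteins Character vector of annotated protein ids.
#' @param n Number of pairs to draw.
#' @param forbidden Data frame with `protein_a`, `protein_b` columns (or
#'   `NULL`) of pairs that must not be drawn.
#' @param seed Integer seed; the sample is reproducible.
#' @return Tibble with columns `protein_a`, `protein_b`.
#' @export
sample_negatives <- function(proteins, n, forbidden = NULL, seed) {
  proteins <- unique(proteins)
  k <- length(proteins)
  forb <- if (is.null(forbidden) || nrow(forbidden) == 0) character() else
    unique(pair_key(forbidden$protein_a, forbidden$protein_b))
  total <- choose(k, 2) - length(forb)
  if (n > total) {
    abort(paste0("requested ", n, " negative pairs but only ", total,
                 " distinct non-forbidden pairs exist"))
  }
  withr::with_seed(seed, {
    if (choose(k, 2) <= 2e5) {
      all_pairs <- utils::combn(sort(proteins), 2)
      keys <- pair_key(all_pairs[1, ], all_pairs[2, ])
      ok <- which(!keys %in% forb)
      pick <- sample(ok, n)
      tibble(protein_a = all_pairs[1, pick], protein_b = all_pairs[2, pick])
    } else {
      got <- character(0)
      out_a <- character(0)
      out_b <- character(0)
      while (length(out_a) < n) {
        a <- sample(proteins, n)
        b <- sample(proteins, n)
        keep <- a != b
        keys <- pair_key(a[keep], b[keep])
        fresh <- !keys %in% forb & !keys %in% got & !duplicated(keys)
        out_a <- c(out_a, pmin(a[keep], b[keep])[fresh])
        out_b <- c(out_b, pmax(a[keep], b[keep])[fresh])
        got <- c(got, keys[fresh])
      }
      tibble(protein_a = out_a[1:n], protein_b = out_b[1:n])
    }
  })
}

#' ROC curve and AUC from labelled scores
#'
#' AUC is computed as the Mann-Whitney rank statistic: the fraction of
#' (positive, negative) score pairs ordered correctly, ties counting one
#' half. ROC points are produced at every distinct score threshold.
#'
#' @param pos,neg Numeric score vectors for the positive and negative class.
#' @return An object of class `gosim_roc`: list with `auc`, `roc` (tibble
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both score classes must be nonempty")
  }
  if (anyNA(pos) || anyNA(neg) || any(!is.finite(c(pos, neg)))) {
    abort("scores must be finite and non-missing")
  }
  np <- length(pos)
  nn <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  roc <- tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(s) mean(pos >= s), 0),
    fpr = vapply(c(Inf, thr), function(s) mean(neg >= s), 0)
  )
  structure(list(auc = auc, roc = roc, n_pos = np, n_neg = nn),
            class = "gosim_roc")
}

#' @export
print.gosim_roc <- function(x, ...) {
  cat("<gosim_roc> AUC ", format(x$auc, digits = 5), " (",
      x$n_pos, " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' @method tidy gosim_roc
#' @export
tidy.gosim_roc <- function(x, ...) x$roc

#' @method glance gosim_roc
#' @export
glance.gosim_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method autoplot gosim_roc
#' @export
autoplot.gosim_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.4f)", object$auc)
    )
}

#' Pearson correlation between two score vectors
#'
#' @param x,y Equal-length numeric vectors (e.g. a functional similarity
#'   column and a reference sequence/Pfam/EC similarity column).
#' @return The product-moment correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("score vectors must have equal length")
  if (length(x) < 2) abort("correlation needs at least two observations")
  if (anyNA(x) || anyNA(y)) abort("scores must be non-missing")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a zero-variance score vector")
  }
  stats::cor(x, y)
}

#' Louvain clustering of a weighted graph
#'
#' Modularity-maximising community detection (Blondel et al. heuristic, via
#' igraph). The run is made reproducible by seeding the RNG; isolated nodes
#' (listed in `nodes` but absent from the edge list) become singletons.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b` and
#'   optionally `weight` (default 1); weights must be non-negative.
#' @param seed Integer seed.
#' @param nodes Optional character vector of the full node universe.
#' @return Tibble with columns `node`, `cluster` (integer labels).
#' @export
cluster_graph <- function(edges, seed, nodes = NULL) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0 && is.null(nodes)) abort("empty graph")
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(edges$weight < 0)) abort("edge weights must be non-negative")
  universe <- unique(c(edges$protein_a, edges$protein_b, nodes))
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b", "weight")],
    directed = FALSE,
    vertices = sort(universe)
  )
  memb <- withr::with_seed(seed, igraph::cluster_louvain(g)$membership)
  tibble(node = igraph::V(g)$name, cluster = as.integer(memb))
}

#' Compare two partitions of the same protein set
#'
#' Builds the contingency table between the ground-truth partition and a
#' clustering result and derives entropies (natural log over cluster-size
#' proportions), mutual information, normalised mutual information and the
#' Rand index of pairwise cluster memberships.
#'
#' @param g,c Partitions over the same universe: either named vectors
#'   (names = nodes, values = cluster labels) or data frames with columns
#'   `node`, `cluster`.
#' @param nmi_norm `"sum"` (default) for `NMI = 2I/(H_g + H_c)`, or
#'   `"sqrt"` for `I/sqrt(H_g * H_c)`. Both define NMI = 1 when both
#'   entropies vanish.
#' @return An object of class `partition_comparison`: list with `n`,
#'   `contingency`, `h_g`, `h_c`, `mi`, `nmi`, `rand_index`, `nmi_norm`.
#' @export
compare_partitions <- function(g, c, nmi_norm = "sum") {
  nmi_norm <- match.arg(nmi_norm, c("sum", "sqrt"))
  as_membership <- function(p) {
    if (is.data.frame(p)) setNames(p$cluster, p$node) else p
  }
  g <- as_membership(g)
  c <- as_membership(c)
  if (length(g) != length(c) || !setequal(names(g), names(c))) {
    abort("partitions must cover the same protein universe")
  }
  c <- c[names(g)]
  n <- length(g)
  tab <- table(g, c)
  ni <- rowSums(tab)
  nj <- colSums(tab)

  entropy <- function(sizes) {
    p <- sizes[sizes > 0] / n
    -sum(p * log(p))
  }
  h_g <- entropy(ni)
  h_c <- entropy(nj)

  nij <- as.vector(tab)
  ei <- rep(ni, times = length(nj))
  ej <- rep(nj, each = length(ni))
  pos <- nij > 0
  mi <- sum((nij[pos] / n) * log(n * nij[pos] / (ei[pos] * ej[pos])))

  nmi <- if (h_g + h_c == 0) 1
         else if (nmi_norm == "sum") 2 * mi / (h_g + h_c)
         else if (h_g * h_c == 0) 0
         else mi / sqrt(h_g * h_c)

  # Rand index: a = co-clustered in both, b = separated in both
  pairs_same <- function(sizes) sum(choose(sizes, 2))
  a <- pairs_same(nij)
  b <- choose(n, 2) - pairs_same(ni) - pairs_same(nj) + a
  ri <- (a + b) / choose(n, 2)

  structure(
    list(n = n, contingency = tab, h_g = h_g, h_c = h_c,
         mi = mi, nmi = nmi, rand_index = ri, nmi_norm = nmi_norm),
    class = "partition_comparison"
  )
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat("<partition_comparison> ", x$n, " proteins, ",
      nrow(x$contingency), " vs ", ncol(x$contingency), " clusters: NMI ",
      format(x$nmi, digits = 5), ", Rand index ",
      format(x$rand_index, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @method glance partition_comparison
#' @export
glance.partition_comparison <- function(x, ...) {
  tibble(n = x$n, h_g = x$h_g, h_c = x$h_c, mi = x$mi,
         nmi = x$nmi, rand_index = x$rand_index)
}

# ICs for each family appearing in a configuration grid, computed once.
family_ic_tables <- function(configs, dag, ann,
                             weights = c(is_a = 0.8, part_of = 0.6)) {
  fams <- unique(stats::na.omit(configs$family))
  setNames(lapply(fams, ic_table, dag = dag, ann = ann, weights = weights),
           fams)
}

#' Functional-coherence AUC of measures on a PPI network
#'
#' Scores the positive (interacting) pairs and an equal-size random negative
#' set with every requested measure configuration and reports the AUC of
#' each. Meaningful for the BP and CC ontologies, where physically
#' interacting proteins are expected to share processes or compartments.
#'
#' @param positives Data frame with columns `protein_a`, `protein_b`; all
#'   proteins must be annotated in `ann`.
#' @param ann A propagated `go_annotation`.
#' @param dag The matching `go_dag`.
#' @param configs Rows of [enumerate_measures()] (default: all 57).
#' @param seed Integer seed for negative sampling.
#' @param termset Passed to [funcsim()].
#' @return Tibble with columns `label`, `auc`, `n_pos`, `n_neg`.
#' @export
eval_ppi <- function(positives, ann, dag, configs = enumerate_measures(),
                     seed, termset = "direct") {
  positives <- as_tibble(positives)
  prots <- unique(c(positives$protein_a, positives$protein_b))
  missing <- setdiff(prots, annotated_proteins(ann))
  if (length(missing) > 0) {
    abort(paste0("positive-set protein(s) unannotated in namespace ",
                 ann$namespace, ": ", paste(head(missing, 3), collapse = ", ")))
  }
  negatives <- sample_negatives(annotated_proteins(ann), nrow(positives),
                                forbidden = positives, seed = seed)
  ics <- family_ic_tables(configs, dag, ann)
  purrr::pmap_dfr(configs, function(label, family, functional, termsim, xgrasm) {
    cfg <- list(label = label, family = family, functional = functional,
                termsim = termsim, xgrasm = xgrasm)
    ic <- if (is.na(family)) NULL else ics[[family]]
    pos <- funcsim_pairs(ann, dag, ic, positives, cfg, termset)$score
    neg <- funcsim_pairs(ann, dag, ic, negatives, cfg, termset)$score
    tibble(label = label, auc = roc_auc(pos, neg)$auc,
           n_pos = length(pos), n_neg = length(neg))
  })
}

#' Clustering power of measures on a co-expression network
#'
#' The ground truth is the Louvain partition of the original weighted graph.
#' For each measure configuration the edges are re-weighted by functional
#' similarity, the graph re-clustered with the same seed, and the result
#' compared to the ground truth. Intended for the BP ontology, where
#' co-expressed genes are expected to share processes.
#'
#' @param edges Data frame with `protein_a`, `protein_b`, `weight`.
#' @inheritParams eval_ppi
#' @param nmi_norm Passed to [compare_partitions()].
#' @return Tibble with columns `label`, `nmi`, `rand_index`.
#' @export
eval_clustering <- function(edges, ann, dag, configs = enumerate_measures(),
                            seed, termset = "direct", nmi_norm = "sum") {
  edges <- as_tibble(edges)
  truth <- cluster_graph(edges, seed)
  ics <- family_ic_tables(configs, dag, ann)
  purrr::pmap_dfr(configs, function(label, family, functional, termsim, xgrasm) {
    cfg <- list(label = label, family = family, functional = functional,
                termsim = termsim, xgrasm = xgrasm)
    ic <- if (is.na(family)) NULL else ics[[family]]
    scored <- funcsim_pairs(ann, dag, ic, edges, cfg, termset)
    reweighted <- tibble(protein_a = scored$protein_a,
                         protein_b = scored$protein_b,
                         weight = scored$score)
    part <- cluster_graph(reweighted, seed, nodes = truth$node)
    cmp <- compare_partitions(truth, part, nmi_norm)
    tibble(label = label, nmi = cmp$nmi, rand_index = cmp$rand_index)
  })
}

#' Plot per-measure evaluation results
#'
#' Bar chart of an evaluation metric (AUC, NMI or Rand index) across measure
#' labels, in the style of a per-measure performance figure.
#'
#' @param results Tibble from [eval_ppi()] or [eval_clustering()].
#' @param metric Column to plot (default: the first metric column present).
#' @return A ggplot object.
#' @export
plot_measure_eval <- function(results, metric = NULL) {
  metric <- metric %||%
    intersect(c("auc", "nmi", "rand_index"), names(results))[1]
  ggplot2::ggplot(results,
                  ggplot2::aes(x = stats::reorder(.data$label, .data[[metric]]),
                               y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric)
}
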