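# Synthetic ontologies, annotation corpora and evaluation instances.
#
# Everything downstream is testable without downloads: rooted multi-parent
# DAGs with mixed is_a/part_of edges, Zipf-skewed annotation corpora obeying
# the true-path rule, planted positive/negative protein-pair sets, and
# planted-community weighted co-expression graphs.  All generators are pure
# functions of (spec, seed): the same seed reproduces the same instance.

#' Parameters for the synthetic generators
#'
#' Defaults describe a small but structurally realistic instance: a 250-term
#' DAG with occasional extra parents and part_of edges, and a 200-protein
#' corpus with Zipf-skewed term popularity (real GO corpora are dominated by
#' a few popular terms) in which the term vocabulary is much larger than any
#' one protein's annotation set — the regime real GO corpora live in, and
#' the one that makes a shared specific term informative.
#'
#' @param n_terms Number of ontology terms (including the root); >= 2.
#' @param p_extra Probability that a non-root term receives one extra parent.
#' @param p_partof Probability that an edge is typed `part_of` rather than
#'   `is_a`.
#' @param n_proteins Corpus size.
#' @param mean_terms Poisson mean; each protein gets `1 + Poisson(mean_terms)`
#'   direct terms.
#' @param zipf_alpha Skew of term popularity (0 = uniform).
#' @param signal Planted positive-pair signal strength in \[0, 1\]: the
#'   probability that a positive pair is forced to share a direct term.
#' @param n_pairs Positive (and negative) pairs for [planted_ppi()].
#' @param n_communities,community_size Planted-partition layout for
#'   [planted_coexpression()].
#' @param p_within,p_between Edge probabilities inside/between communities.
#' @param seed Mandatory integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_terms = 250, p_extra = 0.2, p_partof = 0.2,
                       n_proteins = 200, mean_terms = 1, zipf_alpha = 1,
                       signal = 1, n_pairs = 50,
                       n_communities = 2, community_size = 20,
                       p_within = 0.9, p_between = 0.05, seed) {
  if (missing(seed)) abort("synth_spec requires an explicit seed")
  stopifnot(n_terms >= 2,
            p_extra >= 0, p_extra <= 1,
            p_partof >= 0, p_partof <= 1,
            p_within >= 0, p_within <= 1,
            p_between >= 0, p_between <= 1,
            signal >= 0, signal <= 1)
  structure(
    list(n_terms = n_terms, p_extra = p_extra, p_partof = p_partof,
         n_proteins = n_proteins, mean_terms = mean_terms,
         zipf_alpha = zipf_alpha, signal = signal, n_pairs = n_pairs,
         n_communities = n_communities, community_size = community_size,
         p_within = p_within, p_between = p_between, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' The worked six-term fixture
#'
#' A hand-checkable ontology and corpus used as the package's golden
#' fixture: terms R (root), A, B, C, D, E with edges A is_a R, B is_a R,
#' C is_a A, C is_a B, D part_of A, E is_a A, E is_a B; proteins p1..p5
#' directly annotated to C, D, B, A, E respectively. Built by round-tripping
#' OBO and GAF text through the package's own parsers.
#'
#' @return List with `dag` (a `go_dag`), `ann` (a propagated
#'   `go_annotation`), `obo` and `gaf` (the source text).
#' @examples
#' fx <- fixture_F1()
#' sort(ancestors(fx$dag, "C"))
#' @export
fixture_F1 <- function() {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: R", "name: root", "namespace: biological_process", "",
    "[Term]", "id: A", "name: term A", "namespace: biological_process",
    "is_a: R", "",
    "[Term]", "id: B", "name: term B", "namespace: biological_process",
    "is_a: R", "",
    "[Term]", "id: C", "name: term C", "namespace: biological_process",
    "is_a: A", "is_a: B", "",
    "[Term]", "id: D", "name: term D", "namespace: biological_process",
    "relationship: part_of A", "",
    "[Term]", "id: E", "name: term E", "namespace: biological_process",
    "is_a: A", "is_a: B", ""
  )
  gaf <- c(
    "!gaf-version: 2.2",
    paste("SYNDB", c("p1", "p2", "p3", "p4", "p5"),
          c("p1", "p2", "p3", "p4", "p5"), "enables",
          c("C", "D", "B", "A", "E"), "SYN:0000001", "IEA", "", "P",
          c("p1", "p2", "p3", "p4", "p5"), "", "protein", "taxon:9606",
          "20260101", "SYNDB", "", "", sep = "\t")
  )
  dag <- parse_obo(obo)$BP
  ann <- propagate(parse_gaf(gaf, list(BP = dag))$BP, dag)
  list(dag = dag, ann = ann, obo = obo, gaf = gaf)
}

#' Random rooted DAG
#'
#' Term `i > 1` receives one parent uniformly among terms `1..i-1` plus,
#' with probability `p_extra`, one additional distinct earlier parent; edge
#' types are `part_of` with probability `p_partof`. Parents always precede
#' children in creation order, so the graph is acyclic by construction and
#' has the first term as its unique root.
#'
#' @param spec A [synth_spec()].
#' @param seed Optional override of `spec$seed`.
#' @param namespace Ontology aspect for the generated DAG.
#' @return A `go_dag`.
#' @export
random_dag <- function(spec, seed = spec$seed, namespace = "BP") {
  n <- spec$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  withr::with_seed(seed, {
    child <- character(0)
    parent <- character(0)
    for (i in 2:n) {
      ps <- if (i == 2) 1L else sample.int(i - 1L, 1L)
      if (i > 2 && runif(1) < spec$p_extra) {
        extra <- sample.int(i - 1L, 1L)
        if (extra != ps) ps <- c(ps, extra)
      }
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
    }
    type <- ifelse(runif(length(child)) < spec$p_partof, "part_of", "is_a")
    new_go_dag(
      tibble(id = ids, name = paste("synthetic term", seq_len(n))),
      tibble(child = child, parent = parent, type = type),
      namespace
    )
  })
}

# Zipf-style popularity weights over the non-root terms, in creation order.
zipf_weights <- function(dag, alpha) {
  ts <- setdiff(dag$topo, dag$root)
  ts <- sort(ts)  # creation order == lexicographic for generated ids
  w <- seq_along(ts)^(-alpha)
  setNames(w / sum(w), ts)
}

#' Random Zipf-skewed annotation corpus
#'
#' Each protein receives `1 + Poisson(mean_terms)` distinct direct terms
#' sampled from the non-root terms with Zipf(`zipf_alpha`) popularity over
#' creation order, and an evidence code (mostly IEA, as in real GOA).
#' The returned GAF text re-parses to the same annotation set.
#'
#' @param dag A `go_dag`, e.g. from [random_dag()].
#' @param spec A [synth_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return List with `ann` (propagated `go_annotation`) and `gaf` (text).
#' @export
random_annotations <- function(dag, spec, seed = spec$seed) {
  weights <- zipf_weights(dag, spec$zipf_alpha)
  prots <- sprintf("P%05d", seq_len(spec$n_proteins))
  withr::with_seed(seed, {
    records <- purrr::map_dfr(prots, function(p) {
      k <- min(1 + rpois(1, spec$mean_terms), length(weights))
      tibble(protein = p,
             term = sample(names(weights), k, prob = weights),
             evidence = sample(c("IEA", "EXP"), k, replace = TRUE,
                               prob = c(0.9, 0.1)))
    })
  })
  ann <- new_go_annotation(records, dag$namespace)
  gaf <- write_gaf(ann)
  list(ann = propagate(ann, dag), gaf = gaf)
}

#' Planted positive/negative protein-pair sets
#'
#' With probability `signal` a positive pair is planted to be functionally
#' coherent: a term is drawn uniformly among terms with at least two direct
#' annotators and two of its annotators are paired, so positives share at
#' least one direct term (and rare, informative terms contribute as often as
#' popular ones, as shared specific functions do for interacting proteins).
#' Otherwise the pair is uniform random. Negatives are an equal number of
#' uniform random non-positive pairs, mirroring a negative set sampled at
#' random among annotated protein pairs.
#'
#' @param ann A propagated `go_annotation`.
#' @param spec A [synth_spec()] (uses `signal` and `n_pairs`).
#' @param seed Optional override of `spec$seed`.
#' @return List with `positives` and `negatives` tibbles (`protein_a`,
#'   `protein_b`).
#' @export
planted_ppi <- function(ann, spec, seed = spec$seed) {
  prots <- sort(annotated_proteins(ann))
  if (length(prots) < 4) abort("corpus too small to plant protein pairs")
  by_term <- lapply(split(ann$records$protein, ann$records$term), unique)
  by_term <- by_term[lengths(by_term) >= 2]
  n_sharing <- sum(vapply(by_term, function(ps) choose(length(ps), 2), 0))
  if (spec$signal > 0 && n_sharing < spec$n_pairs) {
    abort("too few term-sharing pairs to plant the requested positives")
  }
  n <- spec$n_pairs
  withr::with_seed(seed, {
    use_signal <- runif(n) < spec$signal
    keys <- character(0)
    tries <- 0L
    while (length(keys) < sum(use_signal) && tries < 100L * n) {
      t <- sample(names(by_term), 1)
      ps <- sample(by_term[[t]], 2)
      keys <- unique(c(keys, pair_key(ps[1], ps[2])))
      tries <- tries + 1L
    }
    n_rand <- n - length(keys)
    if (n_rand > 0) {
      rand <- sample_negatives(prots, n_rand, forbidden = NULL,
                               seed = sample.int(2^30, 1))
      keys <- unique(c(keys, pair_key(rand$protein_a, rand$protein_b)))
    }
    split_keys <- strsplit(keys, "\r", fixed = TRUE)
    positives <- tibble(
      protein_a = vapply(split_keys, `[`, "", 1),
      protein_b = vapply(split_keys, `[`, "", 2)
    )
    negatives <- sample_negatives(prots, nrow(positives),
                                  forbidden = positives,
                                  seed = sample.int(2^30, 1))
    list(positives = positives, negatives = negatives)
  })
}

#' Planted-community weighted co-expression graph
#'
#' Builds `n_communities` disjoint subtrees under a common root, annotates
#' each community's proteins only from its own subtree, and wires a
#' planted-partition graph: within-community edges with probability
#' `p_within` and weights in (0.6, 1), between-community edges with
#' probability `p_between` and weights in (0, 0.3).
#'
#' @param spec A [synth_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return List with `edges` (tibble `protein_a`, `protein_b`, `weight`),
#'   `labels` (tibble `node`, `community`), `ann` (propagated BP
#'   `go_annotation`) and `dag`.
#' @export
planted_coexpression <- function(spec, seed = spec$seed) {
  if (spec$n_communities < 2) abort("need at least two planted communities")
  k <- spec$n_communities
  size <- spec$community_size
  terms_per <- max(3, floor((spec$n_terms - 1) / k))

  withr::with_seed(seed, {
    # one subtree per community, all hanging off the root
    ids <- "GO:0000001"
    child <- character(0)
    parent <- character(0)
    comm_terms <- vector("list", k)
    for (ci in seq_len(k)) {
      branch <- sprintf("GO:%d%06d", ci, seq_len(terms_per))
      ids <- c(ids, branch)
      child <- c(child, branch[1])
      parent <- c(parent, "GO:0000001")
      for (j in seq_along(branch)[-1]) {
        child <- c(child, branch[j])
        parent <- c(parent, branch[sample.int(j - 1L, 1L)])
      }
      comm_terms[[ci]] <- branch
    }
    type <- ifelse(runif(length(child)) < spec$p_partof, "part_of", "is_a")
    dag <- new_go_dag(
      tibble(id = ids, name = paste("synthetic term", seq_along(ids))),
      tibble(child = child, parent = parent, type = type),
      "BP"
    )

    prots <- sprintf("P%05d", seq_len(k * size))
    community <- rep(seq_len(k), each = size)
    records <- purrr::map_dfr(seq_along(prots), function(i) {
      pool <- comm_terms[[community[i]]]
      n_t <- min(1 + rpois(1, spec$mean_terms), length(pool))
      tibble(protein = prots[i], term = sample(pool, n_t), evidence = "IEA")
    })
    ann <- propagate(new_go_annotation(records, "BP"), dag)

    pairs <- utils::combn(seq_along(prots), 2)
    same <- community[pairs[1, ]] == community[pairs[2, ]]
    p_edge <- ifelse(same, spec$p_within, spec$p_between)
    keep <- runif(ncol(pairs)) < p_edge
    w <- ifelse(same[keep], runif(sum(keep), 0.6, 1),
                runif(sum(keep), 0, 0.3))
    edges <- tibble(
      protein_a = prots[pairs[1, keep]],
      protein_b = prots[pairs[2, keep]],
      weight = w
    )
    list(edges = edges,
         labels = tibble(node = prots, community = community),
         ann = ann, dag = dag)
  })
}
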