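# Shared fixture and independent brute-force oracles used by the
# oracle-equivalence tests.  The oracles deliberately avoid the package's
# precomputed closures: they follow raw parent/child edges step by step.

F1 <- fixture_F1()

# Transitive closure by naive repeated edge-following over dag$parents.
naive_ancestors <- function(dag, t, inclusive = TRUE) {
  seen <- t
  frontier <- t
  repeat {
    nxt <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                   seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (inclusive) seen else setdiff(seen, t)
}

naive_descendants <- function(dag, t, inclusive = TRUE) {
  seen <- t
  frontier <- t
  repeat {
    nxt <- setdiff(unique(unlist(dag$children[frontier], use.names = FALSE)),
                   seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (inclusive) seen else setdiff(seen, t)
}

# Annotation IC by direct counting: for each term, the proteins directly
# annotated to any inclusive descendant (equivalently, whose extended set
# contains the term), without using propagate().
oracle_annotation_ic <- function(ann, dag) {
  direct <- split(ann$records$protein, ann$records$term)
  prots <- unique(ann$records$protein)
  counts <- vapply(dag$topo, function(t) {
    ds <- naive_descendants(dag, t)
    length(unique(unlist(direct[ds], use.names = FALSE)))
  }, 0L)
  counts <- counts[counts > 0]
  -log(counts / length(prots))
}

# AUC by exhaustive enumeration of ordered positive x negative score pairs.
oracle_auc <- function(pos, neg) {
  grid <- expand.grid(p = pos, n = neg)
  mean((grid$p > grid$n) + 0.5 * (grid$p == grid$n))
}

random_instance <- function(seed, n_terms = 20, n_proteins = 15) {
  spec <- synth_spec(n_terms = n_terms, n_proteins = n_proteins,
                     p_extra = 0.3, p_partof = 0.3, seed = seed)
  dag <- random_dag(spec)
  corpus <- random_annotations(dag, spec)
  list(dag = dag, ann = corpus$ann, spec = spec)
}
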