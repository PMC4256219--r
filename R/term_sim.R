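# Term-level semantic similarity.
#
# All node-based models are instances of one pattern: a commonality statistic
# S over the shared ancestors of the pair, normalised by the descriptions of
# the two terms.  With MICA = most informative common ancestor:
#   resnik     S
#   lin        2S / (IC(t1)+IC(t2))
#   nunivers   S / max(IC(t1), IC(t2))
#   relevance  lin * (1 - exp(-S))      (under annotation IC, 1 - p(MICA))
#   li         lin * (1 - 1/(1+S))
# XGraSM replaces IC(MICA) by the mean IC over ALL informative (IC > 0)
# common ancestors.  Wang's hybrid formula instead sums the S-value
# contributions of shared ancestors relative to both terms' semantic values.

TERM_SIM_MODELS <- c("resnik", "lin", "nunivers", "relevance", "li", "wang")

#' Shared-ancestor context of a term pair
#'
#' Computes the inclusive common-ancestor set, the most informative common
#' ancestor (MICA; ties broken by lexicographically smallest id) and the
#' informative commons (shared ancestors with IC > 0, which excludes the root
#' under the annotation, Zhang and universal models).
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic` covering both terms.
#' @param t1,t2 Term ids (same namespace).
#' @return List with `t1`, `t2`, `common` (character), `mica` (term id),
#'   `informative` (character).
#' @export
pair_context <- function(dag, ic, t1, t2) {
  t1 <- resolve_term(dag, t1)
  t2 <- resolve_term(dag, t2)
  common <- intersect(dag$anc[[t1]], dag$anc[[t2]])
  ics <- vapply(common, function(a) ic_value(ic, a), 0)
  cand <- sort(common[ics == max(ics)])
  list(
    t1 = t1, t2 = t2,
    common = common,
    mica = cand[1],
    informative = common[ics > 0]
  )
}

#' Term semantic similarity
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic`; must be a Wang table for `model = "wang"`.
#' @param t1,t2 Term ids.
#' @param model One of `"resnik"`, `"lin"`, `"nunivers"`, `"relevance"`,
#'   `"li"`, `"wang"`.
#' @param xgrasm Use the mean IC over all informative common ancestors in
#'   place of the MICA IC. Not defined for the Wang hybrid model.
#' @return Numeric score. `lin`, `nunivers`, `relevance`, `li` and `wang` lie
#'   in \[0, 1\]; `resnik` is bounded by the maximum IC.
#' @examples
#' fx <- fixture_F1()
#' ic <- ic_annotation(fx$ann, fx$dag)
#' term_sim(fx$dag, ic, "C", "E", "lin")
#' @export
term_sim <- function(dag, ic, t1, t2, model, xgrasm = FALSE) {
  model <- match.arg(model, TERM_SIM_MODELS)
  if (model == "wang") {
    if (xgrasm) abort("XGraSM is not defined for the Wang hybrid model")
    return(term_sim_wang(dag, ic, t1, t2))
  }
  ctx <- pair_context(dag, ic, t1, t2)
  s <- if (xgrasm) {
    if (length(ctx$informative) == 0) 0
    else mean(vapply(ctx$informative, function(a) ic_value(ic, a), 0))
  } else {
    ic_value(ic, ctx$mica)
  }
  ic1 <- ic_value(ic, ctx$t1)
  ic2 <- ic_value(ic, ctx$t2)
  lin <- if (ic1 + ic2 == 0) 0 else 2 * s / (ic1 + ic2)
  switch(model,
    resnik = s,
    lin = lin,
    nunivers = if (max(ic1, ic2) == 0) 0 else s / max(ic1, ic2),
    relevance = lin * (1 - exp(-s)),
    li = lin * (1 - 1 / (1 + s))
  )
}

term_sim_wang <- function(dag, ic, t1, t2) {
  if (ic$model != "wang") {
    abort("the Wang hybrid model requires a Wang S-value IC table")
  }
  t1 <- resolve_term(dag, t1)
  t2 <- resolve_term(dag, t2)
  common <- intersect(dag$anc[[t1]], dag$anc[[t2]])
  s1 <- ic$aux$svalues[[t1]]
  s2 <- ic$aux$svalues[[t2]]
  sum(s1[common] + s2[common]) / (ic$values[[t1]] + ic$values[[t2]])
}

#' Pairwise term-similarity matrix for two term sets
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic`.
#' @param terms1,terms2 Character vectors of term ids (the direct annotation
#'   sets of two proteins).
#' @inheritParams term_sim
#' @return An `m x n` numeric matrix with `dimnames = list(terms1, terms2)`.
#' @export
term_sim_matrix <- function(dag, ic, terms1, terms2, model, xgrasm = FALSE) {
  if (length(terms1) == 0 || length(terms2) == 0) {
    abort("term-similarity matrix requires nonempty term sets")
  }
  m <- matrix(0, length(terms1), length(terms2),
              dimnames = list(terms1, terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      m[i, j] <- term_sim(dag, ic, terms1[i], terms2[j], model, xgrasm)
    }
  }
  m
}
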