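# Term information-content models.
#
# Four families, all in natural-log units:
#   annotation  IC(t) = -ln( n(t) / n(root) ), n = distinct annotated proteins
#                after true-path propagation (corpus-dependent);
#   zhang       IC(t) = -ln( D(t) / D(root) ), D = inclusive descendant count;
#   universal   IC(t) = -ln( rho(t) ), rho(root)=1,
#                rho(t) = max over parents q of rho(q)/|children(q)|;
#   wang        IC(t) = SV(t) = sum of the S-values t propagates to itself and
#                its ancestors (S_t(t)=1, attenuated per edge by a type weight).
# The first three vanish at the root and increase towards the leaves; Wang's
# SV is >= 1 everywhere and carries the per-term S-value maps needed by the
# Wang hybrid term similarity.

new_go_ic <- function(model, values, aux = NULL) {
  structure(list(model = model, values = values, aux = aux), class = "go_ic")
}

#' @export
print.go_ic <- function(x, ...) {
  cat("<go_ic> model ", x$model, ": ", length(x$values), " terms, max IC ",
      format(max(x$values), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Tidy an IC table
#'
#' @param x A `go_ic`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `ic`, `model`.
#' @method tidy go_ic
#' @export
tidy.go_ic <- function(x, ...) {
  tibble(term = names(x$values), ic = unname(x$values), model = x$model)
}

ic_value <- function(ic, term) {
  if (!term %in% names(ic$values)) {
    if (ic$model == "annotation") {
      abort(paste0("term ", term, " is not in the annotation corpus"))
    }
    abort(paste0("term ", term, " has no IC value under model ", ic$model))
  }
  ic$values[[term]]
}

#' Annotation-frequency information content
#'
#' `IC(t) = -ln(n(t)/N)` where `n(t)` counts distinct proteins whose
#' propagated annotation set contains `t` and `N = n(root)` is the corpus
#' size. Terms annotating no protein are absent from the table; querying them
#' later is an error, never a silent zero.
#'
#' @param ann A `go_annotation` (propagated, or it is propagated here).
#' @param dag The matching `go_dag`.
#' @return A `go_ic` with `model = "annotation"`.
#' @export
ic_annotation <- function(ann, dag) {
  if (is.null(ann$term_counts)) ann <- propagate(ann, dag)
  n_root <- ann$term_counts[[dag$root]]
  if (is.null(n_root) || n_root == 0) abort("empty annotation corpus")
  vals <- -log(ann$term_counts / n_root)
  new_go_ic("annotation", vals[order(names(vals))])
}

#' Zhang descendant-count information content
#'
#' The D-value of a term is the size of its inclusive descendant set;
#' `IC(t) = -ln(D(t)/D(root))`, a Seco-style log-ratio driven purely by
#' topology.
#'
#' @param dag A `go_dag`.
#' @return A `go_ic` with `model = "zhang"`.
#' @export
ic_zhang <- function(dag) {
  d <- lengths(dag$desc)
  new_go_ic("zhang", -log(d / d[[dag$root]]))
}

#' GO-universal topological information content
#'
#' The topological position characteristic rho is 1 at the root and
#' `rho(t) = max over parents q of rho(q) / |children(q)|`, computed in
#' topological order; `IC(t) = -ln(rho(t))`.
#'
#' @param dag A `go_dag`.
#' @return A `go_ic` with `model = "universal"`.
#' @export
ic_universal <- function(dag) {
  rho <- setNames(numeric(length(dag$topo)), dag$topo)
  rho[[dag$root]] <- 1
  nchild <- lengths(dag$children)
  for (t in dag$topo) {
    ps <- dag$parents[[t]]
    if (length(ps) > 0) {
      rho[[t]] <- max(rho[ps] / nchild[ps])
    }
  }
  new_go_ic("universal", -log(rho))
}

#' Wang S-value information content
#'
#' Each term contributes an S-value of 1 to itself; moving up one edge
#' multiplies the S-value by the edge-type weight, and a term reached along
#' several paths keeps the maximum. The semantic value `SV(t)` is the sum of
#' S-values over the inclusive ancestor set and serves as the IC. The
#' per-term S-value maps are retained in `aux$svalues` for the Wang hybrid
#' term similarity.
#'
#' @param dag A `go_dag`.
#' @param weights Named contribution factors per edge type, each in (0,1).
#' @return A `go_ic` with `model = "wang"`; `values` are the SV(t) and
#'   `aux$svalues[[t]]` the named S-value map of `t`.
#' @export
ic_wang <- function(dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (any(weights <= 0 | weights >= 1)) {
    abort("wang edge weights must lie strictly between 0 and 1")
  }
  svalues <- vector("list", length(dag$topo))
  names(svalues) <- dag$topo
  sv <- setNames(numeric(length(dag$topo)), dag$topo)
  rev_topo <- rev(dag$topo)
  for (t in dag$topo) {
    anc_t <- dag$anc[[t]]
    s <- setNames(numeric(length(anc_t)), anc_t)
    s[[t]] <- 1
    for (z in rev_topo[rev_topo %in% anc_t]) {
      if (z == t) next
      cs <- dag$children[[z]]
      ty <- dag$child_types[[z]]
      on_path <- cs %in% anc_t
      s[[z]] <- max(weights[ty[on_path]] * s[cs[on_path]])
    }
    svalues[[t]] <- s
    sv[[t]] <- sum(s)
  }
  new_go_ic("wang", sv, aux = list(svalues = svalues, weights = weights))
}

#' Compute the IC table for a measure family
#'
#' Convenience dispatcher used by the evaluation pipelines: `"annotation"`
#' needs the corpus, the three topology models only the DAG.
#'
#' @param family One of `"annotation"`, `"zhang"`, `"wang"`, `"universal"`.
#' @param dag A `go_dag`.
#' @param ann A `go_annotation` (required for `"annotation"`).
#' @param weights Edge weights forwarded to [ic_wang()].
#' @return A `go_ic`.
#' @export
ic_table <- function(family, dag, ann = NULL,
                     weights = c(is_a = 0.8, part_of = 0.6)) {
  switch(family,
    annotation = {
      if (is.null(ann)) abort("annotation IC requires an annotation corpus")
      ic_annotation(ann, dag)
    },
    zhang = ic_zhang(dag),
    wang = ic_wang(dag, weights),
    universal = ic_universal(dag),
    abort(paste0("unknown IC family: ", family))
  )
}
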