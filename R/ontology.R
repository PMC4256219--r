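# GO DAG container and structural queries.
#
# A `go_dag` holds one namespace (BP, MF or CC) of the ontology as a rooted
# DAG with typed child->parent edges (is_a, part_of).  Ancestor and descendant
# closures are materialised at construction time in topological order, so all
# downstream queries are table lookups.

GO_NAMESPACES <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC",
  BP = "BP", MF = "MF", CC = "CC"
)

#' Construct a GO DAG from term and edge tables
#'
#' Low-level constructor used by [parse_obo()] and the synthetic generators.
#' Validates acyclicity and the single-root property, then precomputes the
#' topological order and the inclusive ancestor/descendant closure of every
#' term.
#'
#' @param terms Data frame with columns `id` and `name`, one row per term.
#' @param edges Data frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`); may have zero rows for a single-term ontology.
#' @param namespace Ontology aspect: `"BP"`, `"MF"` or `"CC"`.
#' @param obsolete Optional data frame (`id`, `name`) of obsolete terms kept
#'   for lookup only; they take no part in the graph.
#' @param alt Optional named character vector mapping alternate accessions to
#'   primary term ids.
#'
#' @return An object of class `go_dag` with elements `namespace`, `root`,
#'   `terms` (tibble), `edges` (tibble), `parents`/`parent_types`,
#'   `children`/`child_types` (named lists), `topo` (topological order,
#'   parents first), `anc`/`desc` (named lists of inclusive closures),
#'   `obsolete` and `alt`.
#' @export
new_go_dag <- function(terms, edges, namespace,
                       obsolete = NULL, alt = NULL) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    edges <- tibble(child = character(), parent = character(),
                    type = character())
  }
  namespace <- unname(GO_NAMESPACES[[namespace]])
  if (anyDuplicated(terms$id)) {
    abort(paste0("duplicate term id: ",
                 terms$id[duplicated(terms$id)][1]))
  }
  missing_parent <- setdiff(edges$parent, terms$id)
  if (length(missing_parent) > 0) {
    abort(paste0("edge references undefined parent term: ",
                 missing_parent[1]))
  }
  missing_child <- setdiff(edges$child, terms$id)
  if (length(missing_child) > 0) {
    abort(paste0("edge references undefined child term: ",
                 missing_child[1]))
  }
  bad_type <- setdiff(unique(edges$type), c("is_a", "part_of"))
  if (length(bad_type) > 0) {
    abort(paste0("unsupported edge type: ", bad_type[1]))
  }
  edges <- dplyr::distinct(edges)

  ids <- terms$id
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  parent_types <- split(edges$type, factor(edges$child, levels = ids))
  children <- split(edges$child, factor(edges$parent, levels = ids))
  child_types <- split(edges$type, factor(edges$parent, levels = ids))

  topo <- topo_sort_ids(ids, parents)

  roots <- ids[lengths(parents[ids]) == 0]
  if (length(roots) != 1) {
    abort(paste0("namespace ", namespace, " must have exactly one root, found ",
                 length(roots), ": ",
                 paste(head(roots, 3), collapse = ", ")))
  }

  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (t in topo) {
    ps <- parents[[t]]
    anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
  }
  desc <- vector("list", length(ids))
  names(desc) <- ids
  for (t in rev(topo)) {
    cs <- children[[t]]
    desc[[t]] <- unique(c(t, unlist(desc[cs], use.names = FALSE)))
  }

  structure(
    list(
      namespace = namespace,
      root = roots,
      terms = terms,
      edges = edges,
      parents = parents,
      parent_types = parent_types,
      children = children,
      child_types = child_types,
      topo = topo,
      anc = anc,
      desc = desc,
      obsolete = obsolete %||% tibble(id = character(), name = character()),
      alt = alt %||% character()
    ),
    class = "go_dag"
  )
}

# Kahn topological sort; errors with a cycle member if the graph is cyclic.
topo_sort_ids <- function(ids, parents) {
  indeg <- lengths(parents[ids])
  names(indeg) <- ids
  # child lists derived on the fly
  kids <- vector("list", length(ids))
  names(kids) <- ids
  for (t in ids) {
    for (p in parents[[t]]) kids[[p]] <- c(kids[[p]], t)
  }
  queue <- ids[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    t <- queue[1]
    queue <- queue[-1]
    out <- c(out, t)
    for (k in unique(kids[[t]])) {
      indeg[[k]] <- indeg[[k]] - sum(parents[[k]] == t)
      if (indeg[[k]] == 0) queue <- c(queue, k)
    }
  }
  if (length(out) < length(ids)) {
    leftover <- setdiff(ids, out)
    abort(paste0("cycle detected in ontology involving term ", leftover[1]))
  }
  out
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> namespace ", x$namespace, ": ", nrow(x$terms), " terms, ",
      nrow(x$edges), " edges, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' @export
format.go_dag <- function(x, ...) {
  paste0("<go_dag ", x$namespace, ": ", nrow(x$terms), " terms>")
}

# Resolve a user-supplied accession to a primary term id, distinguishing
# obsolete terms from unknown ones.
resolve_term <- function(dag, id) {
  if (id %in% names(dag$anc)) return(id)
  if (id %in% names(dag$alt)) return(unname(dag$alt[[id]]))
  if (id %in% dag$obsolete$id) {
    abort(paste0("term ", id, " is obsolete in namespace ", dag$namespace))
  }
  abort(paste0("term ", id, " is absent from namespace ", dag$namespace))
}

#' Ancestors of a term
#'
#' Transitive closure over `is_a` and `part_of` parent edges. Ancestor sets
#' used throughout the package are inclusive of the query term, so that the
#' commonality of a term with its own ancestor contains the ancestor, and
#' self-similarity normalises to 1.
#'
#' @param dag A [new_go_dag()] object.
#' @param id Term accession (alternate ids are resolved to primaries).
#' @param inclusive Include `id` itself? Default `TRUE`.
#' @return Character vector of term ids.
#' @export
ancestors <- function(dag, id, inclusive = TRUE) {
  id <- resolve_term(dag, id)
  out <- dag$anc[[id]]
  if (!inclusive) out <- setdiff(out, id)
  out
}

#' Descendants of a term
#'
#' Mirror of [ancestors()] over child edges.
#'
#' @inheritParams ancestors
#' @return Character vector of term ids.
#' @export
descendants <- function(dag, id, inclusive = TRUE) {
  id <- resolve_term(dag, id)
  out <- dag$desc[[id]]
  if (!inclusive) out <- setdiff(out, id)
  out
}

#' Topological order of a DAG
#'
#' Every parent precedes each of its children; ties are broken by declaration
#' order, so the order is deterministic for a given ontology file.
#'
#' @param dag A [new_go_dag()] object.
#' @return Character vector of all non-obsolete term ids.
#' @export
topological_order <- function(dag) {
  dag$topo
}

#' Tidy a GO DAG into a term table
#'
#' @param x A `go_dag`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `name`, `namespace`, `n_parents`,
#'   `n_children`, `depth` (edge count of the longest path from the root).
#' @method tidy go_dag
#' @export
tidy.go_dag <- function(x, ...) {
  depth <- setNames(rep(0L, length(x$topo)), x$topo)
  for (t in x$topo) {
    ps <- x$parents[[t]]
    if (length(ps) > 0) depth[[t]] <- max(depth[ps]) + 1L
  }
  x$terms |>
    dplyr::mutate(
      namespace = x$namespace,
      n_parents = unname(lengths(x$parents[.data$id])),
      n_children = unname(lengths(x$children[.data$id])),
      depth = unname(depth[.data$id])
    )
}
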