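# OBO 1.2 flat-file reader/writer.
#
# Only the fields the IC measures need are honoured: id, name, namespace,
# alt_id, is_a, relationship: part_of, is_obsolete.  Other relationship
# types (regulates family etc.) are counted and dropped; by default only
# is_a and part_of carry ancestry, matching how these measures are defined.

#' Parse an OBO 1.2 flat file into one DAG per namespace
#'
#' Reads `[Term]` stanzas, builds typed child->parent edges from `is_a` and
#' `relationship: part_of` lines, and returns one rooted [new_go_dag()] per
#' namespace present. Obsolete terms are excluded from the graphs but kept in
#' each DAG's obsolete lookup; `alt_id` accessions resolve silently to their
#' primary id. Edges crossing namespaces are dropped with a warning, and any
#' cycle or dangling parent reference is a hard error.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @param relations Edge types to load as ancestry; default
#'   `c("is_a", "part_of")`. Relationship lines of other types are ignored
#'   with a logged count.
#' @return Named list of `go_dag` objects keyed by namespace code
#'   (`"BP"`, `"MF"`, `"CC"`).
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: root", "namespace: biological_process",
#'          "", "[Term]", "id: GO:2", "name: leaf",
#'          "namespace: biological_process", "is_a: GO:1 ! root")
#' dags <- parse_obo(obo)
#' dags$BP$root
#' @export
parse_obo <- function(x, relations = c("is_a", "part_of")) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s*!.*$", "", lines)   # trailing comments
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  other_starts <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- sort(c(stanza_starts, other_starts, length(lines) + 1L))

  terms <- list()
  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    body <- lines[seq.int(s + 1L, length.out = max(0L, e - s))]
    body <- body[nzchar(body)]
    kv <- regmatches(body, regexpr(":", body), invert = TRUE)
    keys <- trimws(vapply(kv, `[`, "", 1))
    vals <- trimws(vapply(kv, function(p) if (length(p) > 1) p[2] else "", ""))

    id <- vals[keys == "id"][1]
    if (is.na(id)) next
    rel <- vals[keys == "relationship"]
    relsplit <- strsplit(rel, "\\s+")
    terms[[length(terms) + 1L]] <- list(
      id = id,
      name = if (any(keys == "name")) vals[keys == "name"][1] else id,
      namespace = if (any(keys == "namespace")) vals[keys == "namespace"][1] else NA_character_,
      alt_id = vals[keys == "alt_id"],
      is_a = vals[keys == "is_a"],
      rel_type = vapply(relsplit, `[`, "", 1),
      rel_target = vapply(relsplit, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
      obsolete = any(keys == "is_obsolete" & tolower(vals) == "true")
    )
  }
  if (length(terms) == 0) abort("no [Term] stanzas found in OBO input")

  tt <- tibble(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, `[[`, "", "name"),
    namespace = vapply(terms, `[[`, "", "namespace"),
    obsolete = vapply(terms, `[[`, TRUE, "obsolete")
  )
  if (anyDuplicated(tt$id)) {
    abort(paste0("duplicate term id in OBO input: ", tt$id[duplicated(tt$id)][1]))
  }
  ns_of <- setNames(tt$namespace, tt$id)

  edges <- purrr::map_dfr(terms, function(tm) {
    if (tm$obsolete) return(NULL)
    par <- c(tm$is_a, tm$rel_target[tm$rel_type %in% setdiff(relations, "is_a")])
    typ <- c(rep("is_a", length(tm$is_a)),
             tm$rel_type[tm$rel_type %in% setdiff(relations, "is_a")])
    keep <- typ %in% relations
    if (!any(keep)) return(NULL)
    tibble(child = tm$id, parent = par[keep], type = typ[keep])
  })
  n_ignored <- sum(vapply(terms, function(tm) {
    sum(!tm$rel_type %in% relations & !is.na(tm$rel_target))
  }, 0L))
  if (n_ignored > 0) {
    inform(paste0("ignored ", n_ignored,
                  " relationship line(s) of unloaded types"))
  }

  unknown <- setdiff(edges$parent, tt$id)
  if (length(unknown) > 0) {
    abort(paste0("term references undefined parent: ", unknown[1]))
  }
  # drop edges whose parents are obsolete, and cross-namespace edges
  if (nrow(edges) > 0) {
    obs_ids <- tt$id[tt$obsolete]
    edges <- edges[!edges$parent %in% obs_ids, , drop = FALSE]
    cross <- ns_of[edges$child] != ns_of[edges$parent]
    if (any(cross)) {
      warn(paste0("dropping ", sum(cross), " cross-namespace edge(s)"))
      edges <- edges[!cross, , drop = FALSE]
    }
  }

  out <- list()
  for (ns in unique(tt$namespace[!tt$obsolete])) {
    code <- GO_NAMESPACES[[ns]]
    live <- tt[!tt$obsolete & tt$namespace == ns, c("id", "name")]
    obs <- tt[tt$obsolete & tt$namespace == ns, c("id", "name")]
    e <- edges[edges$child %in% live$id, , drop = FALSE]
    alt <- purrr::map_dfr(terms, function(tm) {
      if (tm$obsolete || length(tm$alt_id) == 0 || !tm$id %in% live$id) return(NULL)
      tibble(alt = tm$alt_id, primary = tm$id)
    })
    alt_vec <- if (nrow(alt) > 0) setNames(alt$primary, alt$alt) else character()
    out[[code]] <- new_go_dag(live, e, code, obsolete = obs, alt = alt_vec)
  }
  out
}

#' Serialise DAGs back to OBO 1.2 text
#'
#' Inverse of [parse_obo()] up to field ordering: the emitted text re-parses
#' to structurally identical DAGs.
#'
#' @param dags A single `go_dag` or a named list of them.
#' @return Character vector of OBO lines.
#' @export
write_obo <- function(dags) {
  if (inherits(dags, "go_dag")) dags <- list(dags)
  ns_long <- setNames(names(GO_NAMESPACES)[1:3], c("BP", "MF", "CC"))
  out <- c("format-version: 1.2", "")
  for (dag in dags) {
    for (t in dag$topo) {
      nm <- dag$terms$name[match(t, dag$terms$id)]
      stanza <- c("[Term]",
                  paste0("id: ", t),
                  paste0("name: ", nm),
                  paste0("namespace: ", ns_long[[dag$namespace]]))
      alts <- names(dag$alt)[dag$alt == t]
      stanza <- c(stanza, if (length(alts)) paste0("alt_id: ", alts))
      ps <- dag$parents[[t]]
      ty <- dag$parent_types[[t]]
      for (i in seq_along(ps)) {
        stanza <- c(stanza, if (ty[i] == "is_a") paste0("is_a: ", ps[i])
                            else paste0("relationship: ", ty[i], " ", ps[i]))
      }
      out <- c(out, stanza, "")
    }
    if (nrow(dag$obsolete) > 0) {
      for (i in seq_len(nrow(dag$obsolete))) {
        out <- c(out, "[Term]",
                 paste0("id: ", dag$obsolete$id[i]),
                 paste0("name: ", dag$obsolete$name[i]),
                 paste0("namespace: ", ns_long[[dag$namespace]]),
                 "is_obsolete: true", "")
      }
    }
  }
  out
}
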