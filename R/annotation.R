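# GAF 2.x annotation sets: parsing, evidence filtering and true-path
# propagation.
#
# An annotation set stores, for one namespace, the direct protein -> term
# records (with evidence codes) and, after propagate(), the ancestor-closed
# extended sets plus per-term protein counts.  Counts are over DISTINCT
# proteins: a protein contributes once to a term however many of its direct
# annotations descend from it.

GAF_ASPECT <- c(P = "BP", F = "MF", C = "CC")

new_go_annotation <- function(records, namespace) {
  structure(
    list(
      namespace = namespace,
      records = as_tibble(records),   # protein, term, evidence
      extended = NULL,
      term_counts = NULL
    ),
    class = "go_annotation"
  )
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("<go_annotation> namespace ", x$namespace, ": ",
      length(unique(x$records$protein)), " proteins, ",
      nrow(x$records), " direct annotations",
      if (!is.null(x$extended)) " (propagated)", "\n", sep = "")
  invisible(x)
}

#' Parse a GAF 2.x file into per-namespace annotation sets
#'
#' Uses columns DB_Object_ID (2), Qualifier (4), GO_ID (5), Evidence (7) and
#' Aspect (9). Rows with a `NOT` qualifier are dropped, duplicate
#' protein/term rows are collapsed, GO ids are resolved through each DAG's
#' alt_id table, and ids that are obsolete or unknown are dropped with a
#' logged count (or are an error in strict mode).
#'
#' @param x Path to a GAF file, or a character vector of GAF lines.
#' @param dags Named list of `go_dag` objects from [parse_obo()].
#' @param strict Error (rather than skip with a warning) on malformed lines
#'   and unresolvable GO ids. Default `FALSE`.
#' @return Named list of `go_annotation` objects, one per namespace with at
#'   least one usable annotation. Direct sets only; call [propagate()] before
#'   computing annotation IC.
#' @export
parse_gaf <- function(x, dags, strict = FALSE) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  bad <- lengths(fields) < 9
  if (any(bad)) {
    msg <- paste0(sum(bad), " malformed GAF line(s) (fewer than 9 columns)")
    if (strict) abort(msg) else warn(paste0("skipping ", msg))
    fields <- fields[!bad]
  }
  if (length(fields) == 0) abort("no annotation rows in GAF input")

  rec <- tibble(
    protein = vapply(fields, `[`, "", 2),
    qualifier = vapply(fields, `[`, "", 4),
    term = vapply(fields, `[`, "", 5),
    evidence = vapply(fields, `[`, "", 7),
    aspect = vapply(fields, `[`, "", 9)
  )
  rec <- rec[!grepl("(^|\\|)NOT($|\\|)", rec$qualifier), , drop = FALSE]
  rec$namespace <- unname(GAF_ASPECT[rec$aspect])

  out <- list()
  for (ns in names(dags)) {
    dag <- dags[[ns]]
    r <- rec[!is.na(rec$namespace) & rec$namespace == ns, , drop = FALSE]
    if (nrow(r) == 0) next
    # alt_id resolution, then drop obsolete/unknown terms
    is_alt <- r$term %in% names(dag$alt)
    r$term[is_alt] <- unname(dag$alt[r$term[is_alt]])
    known <- r$term %in% names(dag$anc)
    if (any(!known)) {
      msg <- paste0(sum(!known), " annotation(s) to obsolete/unknown ",
                    ns, " term(s) dropped")
      if (strict) abort(msg) else inform(msg)
      r <- r[known, , drop = FALSE]
    }
    if (nrow(r) == 0) next
    r <- dplyr::distinct(r[, c("protein", "term", "evidence")])
    out[[ns]] <- new_go_annotation(r, ns)
  }
  if (length(out) == 0) abort("no usable annotations in GAF input")
  out
}

#' Filter annotations by evidence code
#'
#' Removes records whose evidence code is in `exclude`; proteins left with no
#' annotations disappear from the corpus (and from `corpus_size`).
#'
#' @param ann A `go_annotation`.
#' @param exclude Character vector of evidence codes, e.g. `"IEA"`.
#' @return A new, unpropagated `go_annotation`.
#' @export
filter_evidence <- function(ann, exclude) {
  stopifnot(inherits(ann, "go_annotation"))
  keep <- !ann$records$evidence %in% exclude
  new_go_annotation(ann$records[keep, , drop = FALSE], ann$namespace)
}

#' True-path propagation of annotations
#'
#' Extends each protein's direct term set with all ancestors (the true-path
#' rule) and tabulates, per term, the number of distinct proteins whose
#' extended set contains it. The root count equals the corpus size.
#'
#' @param ann A `go_annotation` with direct records.
#' @param dag The matching `go_dag`.
#' @return The annotation set with `extended` (named list of term-id vectors)
#'   and `term_counts` (named integer vector) populated.
#' @export
propagate <- function(ann, dag) {
  stopifnot(inherits(ann, "go_annotation"), inherits(dag, "go_dag"))
  if (nrow(ann$records) == 0) abort("cannot propagate an empty annotation set")
  direct <- split(ann$records$term, ann$records$protein)
  ext <- lapply(direct, function(ts) {
    unique(unlist(dag$anc[ts], use.names = FALSE))
  })
  counts <- table(unlist(ext, use.names = FALSE))
  ann$extended <- ext
  ann$term_counts <- setNames(as.integer(counts), names(counts))
  ann
}

# -- accessors -------------------------------------------------------------

#' Direct and extended term sets of a protein
#'
#' @param ann A `go_annotation`.
#' @param protein Protein identifier.
#' @return Character vector of term ids.
#' @export
direct_terms <- function(ann, protein) {
  ts <- unique(ann$records$term[ann$records$protein == protein])
  if (length(ts) == 0) {
    abort(paste0("protein ", protein, " is unannotated in namespace ",
                 ann$namespace))
  }
  ts
}

#' @rdname direct_terms
#' @export
extended_terms <- function(ann, protein) {
  if (is.null(ann$extended)) abort("annotation set is not propagated")
  ts <- ann$extended[[protein]]
  if (is.null(ts)) {
    abort(paste0("protein ", protein, " is unannotated in namespace ",
                 ann$namespace))
  }
  ts
}

#' Annotated proteins of a namespace
#'
#' @param ann A `go_annotation`.
#' @return Character vector of protein ids (the corpus).
#' @export
annotated_proteins <- function(ann) {
  unique(ann$records$protein)
}

#' Tidy an annotation set into per-term counts
#'
#' @param x A propagated `go_annotation`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `n_proteins`, `frequency` (relative to
#'   the corpus size).
#' @method tidy go_annotation
#' @export
tidy.go_annotation <- function(x, ...) {
  if (is.null(x$term_counts)) abort("annotation set is not propagated")
  n <- length(x$extended)
  tibble(
    term = names(x$term_counts),
    n_proteins = unname(x$term_counts),
    frequency = unname(x$term_counts) / n
  ) |>
    dplyr::arrange(dplyr::desc(.data$n_proteins), .data$term)
}

#' Serialise an annotation set to GAF 2.2 text
#'
#' Inverse of [parse_gaf()]: the emitted text re-parses to the same direct
#' annotation records.
#'
#' @param anns A `go_annotation` or named list of them.
#' @param db Database label for column 1.
#' @param taxon Taxon field for column 13.
#' @return Character vector of GAF lines.
#' @export
write_gaf <- function(anns, db = "SYNDB", taxon = "taxon:9606") {
  if (inherits(anns, "go_annotation")) anns <- list(anns)
  aspect_of <- setNames(names(GAF_ASPECT), GAF_ASPECT)
  out <- "!gaf-version: 2.2"
  for (ann in anns) {
    r <- ann$records
    out <- c(out, paste(
      db, r$protein, r$protein, "enables", r$term, "SYN:0000001",
      r$evidence, "", aspect_of[[ann$namespace]], r$protein, "",
      "protein", taxon, "20260101", db, "", "",
      sep = "\t"
    ))
  }
  out
}
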