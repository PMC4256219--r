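# Protein-level functional similarity.
#
# Two routes:
#  * pairwise-term measures (Avg, Max, ABM, BMA) aggregate a term-similarity
#    matrix over the proteins' DIRECT annotation sets;
#  * direct-IC set measures (SimGIC, SimDIC, SimUIC, SimUI) compare the
#    EXTENDED (ancestor-closed) sets: IC-weighted Jaccard, Dice and
#    max-normalised indexes, and the unweighted Jaccard.
# Combined with the IC families these yield the canonical 57-measure grid.

FUNCTIONAL_PAIRWISE <- c("avg", "max", "abm", "bma")
FUNCTIONAL_DIRECT <- c("simgic", "simdic", "simuic", "simui")

#' Aggregate a term-similarity matrix into a protein score
#'
#' With row maxima `r_i` and column maxima `c_j` of the `m x n` matrix:
#' `avg` is the grand mean, `max` the grand maximum,
#' `abm = (sum(r_i) + sum(c_j)) / (m + n)` (the average over all best
#' matches) and `bma = (mean(r_i) + mean(c_j)) / 2` (the mean of the two
#' directional best-match averages). The two coincide when `m = n`.
#'
#' @param simmatrix Numeric matrix of term-pair similarities.
#' @param strategy One of `"avg"`, `"max"`, `"abm"`, `"bma"`.
#' @return Numeric score.
#' @export
pairwise_funcsim <- function(simmatrix, strategy) {
  strategy <- match.arg(strategy, FUNCTIONAL_PAIRWISE)
  if (length(simmatrix) == 0) abort("empty term-similarity matrix")
  simmatrix <- rbind(simmatrix)
  r <- apply(simmatrix, 1, max)
  cc <- apply(simmatrix, 2, max)
  switch(strategy,
    avg = mean(simmatrix),
    max = max(simmatrix),
    abm = (sum(r) + sum(cc)) / (nrow(simmatrix) + ncol(simmatrix)),
    bma = (mean(r) + mean(cc)) / 2
  )
}

#' Direct-IC set measures over extended annotation sets
#'
#' With `I` the summed IC over the intersection of the two extended sets,
#' `U` over the union, and `SA`, `SB` over each set: `simgic = I/U`,
#' `simdic = 2I/(SA+SB)`, `simuic = I/max(SA,SB)`; `simui` is the plain
#' Jaccard index of the sets (equivalently SimGIC under an all-ones IC).
#'
#' @param ext1,ext2 Character vectors: ancestor-closed term sets.
#' @param ic A `go_ic` (ignored for `"simui"`).
#' @param measure One of `"simgic"`, `"simdic"`, `"simuic"`, `"simui"`.
#' @return Numeric score in \[0, 1\].
#' @export
direct_funcsim <- function(ext1, ext2, ic = NULL, measure) {
  measure <- match.arg(measure, FUNCTIONAL_DIRECT)
  if (length(ext1) == 0 || length(ext2) == 0) {
    abort("direct-IC measures require nonempty extended sets")
  }
  inter <- intersect(ext1, ext2)
  if (measure == "simui") {
    return(length(inter) / length(union(ext1, ext2)))
  }
  icsum <- function(ts) {
    if (length(ts) == 0) 0 else sum(vapply(ts, function(t) ic_value(ic, t), 0))
  }
  i <- icsum(inter)
  sa <- icsum(ext1)
  sb <- icsum(ext2)
  denom <- switch(measure,
    simgic = icsum(union(ext1, ext2)),
    simdic = sa + sb,
    simuic = max(sa, sb)
  )
  if (denom == 0) {
    warn("all-zero IC over the compared sets; similarity defined as 0")
    return(0)
  }
  num <- if (measure == "simdic") 2 * i else i
  num / denom
}

#' The 57-measure grid
#'
#' Enumerates every labelled combination of IC family, term-similarity model
#' and protein-level measure: the eight annotation-based term-similarity
#' models (Resnik, Nunivers, Lin and their XGraSM enhancements, Li,
#' Relevance) under the four pairwise strategies; the three topology
#' approaches (Zhang via the Resnik form on Zhang IC, Wang via its hybrid
#' formula, GO-universal via the Nunivers form) under the same strategies;
#' SimGIC/SimDIC/SimUIC under all four IC families; and SimUI. Labels follow
#' the conventional prefixes (R, XR, N, XN, L, XL, Li, S, Z, W, U, A) and
#' suffixes (Avg, ABM, BMA, Max, GIC, DIC, UIC).
#'
#' @return A tibble with 57 rows and columns `label`, `family`, `functional`,
#'   `termsim`, `xgrasm`.
#' @examples
#' nrow(enumerate_measures())
#' @export
enumerate_measures <- function() {
  strategies <- c(Avg = "avg", ABM = "abm", BMA = "bma", Max = "max")

  ann_models <- tibble(
    prefix = c("R", "XR", "N", "XN", "L", "XL", "Li", "S"),
    termsim = c("resnik", "resnik", "nunivers", "nunivers",
                "lin", "lin", "li", "relevance"),
    xgrasm = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
  ann_pairwise <- tidyr::crossing(ann_models,
                                  tibble(suffix = names(strategies))) |>
    dplyr::mutate(
      label = paste0(.data$prefix, .data$suffix),
      family = "annotation",
      functional = unname(strategies[.data$suffix])
    )

  topo_models <- tibble(
    prefix = c("Z", "W", "U"),
    family = c("zhang", "wang", "universal"),
    termsim = c("resnik", "wang", "nunivers"),
    xgrasm = FALSE
  )
  topo_pairwise <- tidyr::crossing(topo_models,
                                   tibble(suffix = names(strategies))) |>
    dplyr::mutate(
      label = paste0(.data$prefix, .data$suffix),
      functional = unname(strategies[.data$suffix])
    )

  direct <- tidyr::crossing(
    tibble(prefix = c("A", "Z", "W", "U"),
           family = c("annotation", "zhang", "wang", "universal")),
    tibble(suffix = c("GIC", "DIC", "UIC"),
           functional = c("simgic", "simdic", "simuic"))
  ) |>
    dplyr::mutate(label = paste0(.data$prefix, .data$suffix),
                  termsim = NA_character_, xgrasm = NA)

  simui <- tibble(label = "SimUI", family = NA_character_,
                  functional = "simui", termsim = NA_character_, xgrasm = NA)

  dplyr::bind_rows(ann_pairwise, topo_pairwise, direct, simui) |>
    dplyr::select("label", "family", "functional", "termsim", "xgrasm")
}

measure_config <- function(label) {
  grid <- enumerate_measures()
  i <- match(label, grid$label)
  if (is.na(i)) {
    abort(paste0("unknown measure label '", label, "'; valid labels: ",
                 paste(grid$label, collapse = ", ")))
  }
  as.list(grid[i, ])
}

#' Functional similarity of two proteins under one measure configuration
#'
#' Pairwise configurations build the term-similarity matrix over the two
#' proteins' direct annotation sets and aggregate it; direct-IC
#' configurations compare the extended sets. Unannotated proteins raise an
#' error rather than scoring 0, so missing annotations can never masquerade
#' as dissimilarity.
#'
#' @param ann A propagated `go_annotation`.
#' @param dag The matching `go_dag`.
#' @param ic A `go_ic` of the configuration's family (`NULL` allowed for
#'   SimUI).
#' @param p1,p2 Protein ids.
#' @param config A measure label (e.g. `"XRBMA"`, `"AGIC"`, `"SimUI"`) or a
#'   single row of [enumerate_measures()].
#' @param termset Term sets used by pairwise strategies: `"direct"`
#'   (default) or `"extended"`.
#' @return Numeric score.
#' @export
funcsim <- function(ann, dag, ic, p1, p2, config, termset = "direct") {
  if (is.character(config)) config <- measure_config(config)
  termset <- match.arg(termset, c("direct", "extended"))
  if (config$functional %in% FUNCTIONAL_DIRECT) {
    direct_funcsim(extended_terms(ann, p1), extended_terms(ann, p2),
                   ic, config$functional)
  } else {
    pick <- if (termset == "direct") direct_terms else extended_terms
    m <- term_sim_matrix(dag, ic, pick(ann, p1), pick(ann, p2),
                         config$termsim, config$xgrasm)
    pairwise_funcsim(m, config$functional)
  }
}

#' Score a list of protein pairs under one measure
#'
#' @param ann A propagated `go_annotation`.
#' @param dag The matching `go_dag`.
#' @param ic A `go_ic` (or `NULL` for SimUI).
#' @param pairs Data frame with columns `protein_a`, `protein_b`.
#' @inheritParams funcsim
#' @return The input tibble with a `score` column appended, rows in input
#'   order.
#' @export
funcsim_pairs <- function(ann, dag, ic, pairs, config, termset = "direct") {
  if (is.character(config)) config <- measure_config(config)
  pairs <- as_tibble(pairs)
  pairs$score <- purrr::map2_dbl(
    pairs$protein_a, pairs$protein_b,
    function(a, b) funcsim(ann, dag, ic, a, b, config, termset)
  )
  pairs
}

#' All-vs-all similarity matrix
#'
#' Symmetric protein-by-protein matrix under one measure configuration; the
#' diagonal equals 1 for the normalised measures.
#'
#' @param ann A propagated `go_annotation`.
#' @param dag The matching `go_dag`.
#' @param ic A `go_ic` (or `NULL` for SimUI).
#' @param proteins Character vector of protein ids; defaults to the corpus.
#' @inheritParams funcsim
#' @return Numeric matrix with protein ids as dimnames.
#' @export
similarity_matrix <- function(ann, dag, ic, config,
                              proteins = annotated_proteins(ann),
                              termset = "direct") {
  if (is.character(config)) config <- measure_config(config)
  n <- length(proteins)
  m <- matrix(0, n, n, dimnames = list(proteins, proteins))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- funcsim(ann, dag, ic, proteins[i], proteins[j], config, termset)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}
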