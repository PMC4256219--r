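---
title: "Models and design choices in gofunsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gofunsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofunsim)
```

# Scope

`gofunsim` computes protein functional similarity from Gene Ontology
annotations using the family of information-content (IC) based measures:
four term-IC models, the node-based term similarity models built on them,
and eight protein-level measures, enumerable as a grid of 57 labelled
configurations. It also implements the statistics used to compare such
measures — ROC/AUC on interaction pair sets, Pearson correlation against
reference similarities, and clustering agreement (entropy, mutual
information, NMI, Rand index) on re-weighted co-expression graphs — and a
synthetic-data module that makes the whole stack testable without any
external download.

Out of scope by design: edge/path-based term similarities, HRSS, SSDD,
graph-kernel protein measures, GraSM/DCA disjunct-ancestor schemes (only
the XGraSM enhancement is provided), random-walk enhancements, OWL
parsing, and GO slim mapping.

# The ontology and annotation layer

An OBO 1.2 file is parsed into one rooted DAG per namespace (BP, MF, CC).
Only `is_a` and `part_of` edges carry ancestry: these are the relations
over which the IC measures are defined, and GO usage contemporaneous with
these measures treated the regulates family as out of scope. Relationship
lines of other types are counted and dropped; the `relations` argument can
widen the set. Obsolete terms are excluded from the graph but kept for
lookup, so a query for one fails with "obsolete" rather than "absent";
`alt_id` accessions resolve silently to their primary id. Cycles and
dangling parent references are hard errors at parse time — every
downstream recursion assumes a DAG.

Ancestor sets are **inclusive** of the query term throughout. This is what
makes the extended annotation set of SimGIC ("terms together with their
ancestors") well defined, gives `sim(t, t) = 1` for the normalised term
models, and lets the commonality of a term with its own ancestor contain
that ancestor.

GAF 2.x annotations are filtered (`NOT` qualifiers dropped, duplicates
collapsed, unknown/obsolete ids dropped with a count) and propagated under
the true-path rule: a protein annotated to a term is annotated to all its
ancestors. Per-term frequencies count **distinct proteins**, not
annotation rows, so duplicate rows and multiple descendants cannot inflate
a term's count; the root count equals the corpus size, and counts are
monotone non-increasing from parent to child. IEA-evidenced annotations
are kept by default — real GOA corpora are dominated by them — and
`filter_evidence()` removes any code set on request, dropping proteins
whose annotations vanish.

# Information-content models

All ICs are in natural-log units. The choice of base only rescales every
IC by the same factor, and the normalised similarity models are invariant
to it.

* **Annotation**: `IC(t) = −ln(n(t)/N)` from propagated distinct-protein
  counts. Terms annotating no protein have *no* value; a similarity query
  touching one raises "term not in corpus" rather than assuming `IC = 0`,
  because a silent zero would quietly deflate similarity scores and bias
  any downstream AUC.
* **Zhang**: `IC(t) = −ln(D(t)/D(root))`, `D` the inclusive descendant
  count — a Seco-style log-ratio transplanted onto the GO DAG. The exact
  D-value formula in the literature is ambiguous; this reconstruction is
  isolated behind the model interface.
* **GO-universal**: `ρ(root) = 1`,
  `ρ(t) = max over parents q of ρ(q)/|children(q)|`, `IC = −ln ρ`,
  computed in topological order. A consequence of the max-over-parents
  form worth knowing: when a term has both a specific and a very generic
  parent, its ρ can exceed the generic parent's, so IC is guaranteed to
  dominate only the *most general* parent, not every parent. This also
  means the Nunivers form on universal IC can exceed 1 on such pairs,
  which the tests assert around rather than hide.
* **Wang**: every term contributes S-value 1 to itself; each step up an
  edge multiplies by the edge-type weight (defaults 0.8 for `is_a`, 0.6
  for `part_of`, the conventional values; configurable), and multiple
  paths keep the maximum. `SV(t)` is the sum over the inclusive ancestor
  set, is 1 at the root and strictly greater than 1 elsewhere, and the
  per-term S-value maps are retained because the Wang hybrid term
  similarity needs them.

# Term and protein similarity

For a pair of terms the shared-ancestor context gives the commonality
statistic `S`: the IC of the most informative common ancestor (MICA; ties
broken deterministically by smallest term id), or under XGraSM the mean IC
over all *informative* common ancestors (IC > 0, which excludes the root).
When exactly one informative common ancestor exists, XGraSM and the plain
model coincide. The models: Resnik returns `S` itself; Lin, Nunivers,
Relevance and Li normalise it as described in the README. Lin and Nunivers
define the both-roots case (both ICs zero) as 0. Relevance's correction
factor `1 − e^{−S}` equals `1 − p(MICA)` under annotation IC; applied to a
topology IC it is a natural extension rather than a claim of the original
formulation, and the same holds for Li. Jiang–Conrath is deliberately
absent: it is a monotone transform of Lin's ingredients (a particular case
of that approach) and adds no cell to the grid.

Protein-level measures split into two routes, and the split matters:

* **Pairwise** (Avg, Max, ABM, BMA) aggregate the m×n term-similarity
  matrix over the two proteins' **direct** annotation sets. ABM averages
  all row and column best matches together, `(Σrᵢ + Σcⱼ)/(m+n)`; BMA
  averages the two directional means, `(mean(rᵢ) + mean(cⱼ))/2`; the two
  coincide exactly when `m = n`. Direct sets are the default because the
  best-match logic is about matching *stated* annotations; `termset =
  "extended"` is available since the original convention is not recorded.
* **Direct-IC** (SimGIC, SimDIC, SimUIC, SimUI) compare the **extended**
  (ancestor-closed) sets, which is what "terms together with their
  ancestors" prescribes. SimUI is exactly SimGIC under an all-ones IC
  table, an identity the tests enforce.

Self-similarity equals 1 exactly where the algebra makes it so: all four
direct-IC measures, and Max/ABM/BMA over term models whose self-similarity
is 1 (Lin, Nunivers with positive-IC terms, the Wang hybrid). Avg dilutes
the diagonal with cross-term entries, and the Relevance/Li correction
factors remain below 1 even on identical terms — claiming `sim(p,p) = 1`
for those would simply be false, so the invariant tests scope it
accordingly.

The 57-measure grid is: 8 annotation-family term models (Resnik, Lin,
Nunivers, their XGraSM variants, Li, Relevance) × 4 pairwise strategies;
the 3 topology approaches × 4 strategies; 4 IC families × 3 IC-weighted
set measures; plus SimUI, which needs no IC. The topology approaches enter
the pairwise cells through declared defaults — Zhang via the Resnik form
on Zhang IC (its authors' original pairing), Wang via its own hybrid
formula, GO-universal via the Nunivers form — all overridable, since the
exact historical pairings for the aggregate cells are not recorded.

# Evaluation protocols

**PPI coherence.** Positives are interacting pairs; negatives are an
equal-size uniform sample of annotated protein pairs excluding the
positives (exclusion is cheap, so it is enforced even though the collision
probability is tiny). AUC is computed as the Mann–Whitney rank statistic —
the probability a positive outscores a negative, ties half — which is
exact and threshold-free; ROC points are emitted at every distinct score.
BP and CC are the meaningful ontologies here: interacting proteins share
processes and compartments, not necessarily molecular functions.

**Clustering power.** The ground truth is the Louvain (Blondel et al.)
partition of the original weighted co-expression graph; each measure
re-weights the edges with functional similarity, the graph is re-clustered
with the same seed, and the partitions are compared. Louvain's node-order
nondeterminism is contracted away by seeding; isolated nodes become
singletons. Entropies use natural logs over cluster-size proportions. The
NMI normalisation is `2I/(H_g + H_c)` (with NMI defined as 1 when both
entropies vanish — two trivial partitions agree); the `I/√(H_g·H_c)`
variant sits behind `nmi_norm = "sqrt"`. The "Rand index of pairwise
cluster memberships" is the standard Rand index: pairs co-clustered in
both plus pairs separated in both, over all pairs.

**Correlation.** Plain product-moment correlation between a similarity
column and a reference (sequence/Pfam/EC) column, with zero-variance input
rejected rather than returning NaN.

# The synthetic-data module

The generators are pure functions of a parameter spec and a seed, and
serialise to OBO/GAF text that re-parses to the identical objects.

* `fixture_F1()` is the frozen six-term, five-protein worked example whose
  every IC, term-similarity and protein-similarity value is hand-derivable
  and asserted in the tests to 1e-4.
* `random_dag()` gives each new term one uniform parent among earlier
  terms (plus an extra parent with probability 0.2, and `part_of` typing
  with probability 0.2) — acyclic and single-rooted by construction.
* `random_annotations()` draws `1 + Poisson(mean)` direct terms per
  protein with Zipf(α = 1) popularity, emulating the skew of real GOA
  corpora where a few terms dominate.
* `planted_ppi()` plants functional coherence term-first: a term with ≥ 2
  annotators is drawn uniformly and two annotators paired, so rare,
  informative terms anchor positives as often as popular ones — the
  signature of interacting proteins sharing *specific* functions. Sampling
  uniformly over sharing pairs instead would concentrate positives on the
  most popular, least informative terms and destroy the separation the
  construction is meant to plant.
* `planted_coexpression()` builds disjoint subtrees under the root,
  annotates each community only from its own subtree, and wires a
  planted-partition graph (within-community edge probability 0.9, weight
  0.6–1; between, 0.05 and 0–0.3).

Default sizes — 250 terms, 200 proteins, one-plus-Poisson(1) annotations,
50 planted pairs, two 20-node communities — were fixed once as a realistic
scaled-down regime: the term vocabulary greatly exceeds any protein's
annotation set, as in real corpora, so sharing a specific term is
informative. Under these conditions the full-signal SimGIC/annotation AUC
is about 0.91 with a seed-to-seed standard deviation near 0.04 (50 + 50
pairs is a small sample), every normalised measure stays above chance, the
zero-signal AUC sits within Mann–Whitney null noise of 0.5, and Louvain
recovers the planted communities exactly.

What passing these tests does **not** show: performance on real GO, where
annotation is incomplete and biased (the shallow-annotation problem),
namespaces are three orders of magnitude larger, and interaction data
carry correlated noise rather than planted uniform signal. The synthetic
corpus validates the *mechanics* — formulas, closures, orderings,
statistics — not biological rankings of the 57 measures.

# Numerical choices and limitations

* Ties in MICA selection break to the smallest term id, so runs are
  reproducible to the byte.
* Zero denominators in the direct-IC measures (possible only when every
  compared term has IC 0) return 0 with a warning rather than NaN.
* Scores are kept at full double precision internally; the CLI rounds TSV
  output to six decimals and records the tool version, the full
  invocation and the seed in `#`-prefixed metadata lines.
* Per-term S-value maps make Wang IC O(n·|ancestors|) per namespace;
  fine at synthetic scale and acceptable for one-off runs on real GO, but
  a production service would cache them.
* Unannotated proteins always raise errors rather than scoring zero —
  silently treating missing annotation as dissimilarity would bias every
  evaluation statistic in this package.
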