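---
title: "Building multidimensional semantic spaces with semcube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multidimensional semantic spaces with semcube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semcube)
```

## The problem

Large text collections — literature abstracts, clinical notes, database
free-text fields — become analyzable once each item is linked to the
concepts of a reference taxonomy (a UMLS-style thesaurus: concepts with
identifiers, semantic types, lexical variants and an is-a hierarchy).
`semcube` implements the full chain from raw text to an OLAP-style
*conceptual map*: documents are annotated by dictionary lookup, reduced to
*multidimensional facts* (at most one concept per semantic dimension), and
cross-dimension associations ("semantic bridges") are mined from contingency
cubes over the fact table. Every stage is a data-returning function, so the
pipeline is scriptable and testable without any rendering layer.

## Taxonomic queries through an interval index

All downstream stages ask subsumption questions (`a ≼ b`: is `a` a
reflexive descendant of `b`?) at high volume, so the taxonomy is compiled
once into an **interval index**. Concepts receive post-order integer labels
over a depth-first traversal (roots and children processed in lexicographic
order, so the index is deterministic); a concept's descendant space (L−) is
the coalesced set of closed intervals covering the labels of its reflexive
descendants, and its ancestor space (L+) is the dual. Queries then never
traverse the graph:

* `a ≼ b` iff `a`'s descendant intervals lie inside `b`'s (equivalently,
  `a`'s own label falls in `b`'s descendant cover);
* common ancestors are read off the intersection of two L+ interval sets.

In a DAG a concept reached through several parents contributes a
non-contiguous label, which is why each space is a *set* of intervals. The
reflexive convention (`c ≼ c`) is deliberate: cube counts of the form
"fact at or below `c`" must include documents assigned exactly at `c`.
Correctness is tested exhaustively against a traversal transitive-closure
oracle on dozens of seeded random DAGs.

## Dimensions and levels

A **dimension** is a disjoint semantic group (Disease, Anatomy, ...) declared
by a selector of semantic types and/or root concepts plus a priority.
Concepts matching several selectors go to the highest-priority dimension
(conflicts are reported); concepts matching none are excluded from facts —
we keep the partition semantics rather than inventing a catch-all, and the
conflict report makes exclusions visible.

Levels within a dimension must satisfy two constraints: no two members of a
level are comparable under `≼` (an antichain, so counts are summarizable),
and each level's members share a super-concept inside the dimension. The
constraints do not pin down a unique construction, so the default stratifies
by **longest-path depth** from the dimension's maximal concepts — this
provably yields antichains (comparable concepts always differ in depth).
When a dimension has several maximal concepts a virtual root level is
prepended so the common-ancestor constraint stays satisfiable. An
alternative mode maps configured semantic types directly to levels for
deployments whose type system already stratifies the taxonomy; its levels
are only antichains if the types cooperate, which `validate_schema()`
checks.

## Dictionary annotation

Text chunks (sentences, by default — the affinity model needs sentence
co-occurrence anyway, and the chunk granularity is otherwise a free choice)
and lexicon strings are compared as bags of words. A string S is scored
against chunk T by

$$\mathrm{rank}(S, T) = \frac{\mathrm{idf}(S) - \mathrm{idf}(S \setminus T)}
{\mathrm{idf}(S)} \cdot \frac{|S \cap T|}{\mathrm{ambiguity}(S)}$$

with `idf` the information content of a bag under a background word model
(default: Shannon form, the sum of −ln p(w); a flat variant that sums raw
probabilities is kept behind `idf_mode = "linear"` for fidelity
experiments, because the information-content reading matches the intended
"amount of information" semantics) and `ambiguity(S)` the number of concepts
carrying S as a lexical variant. Out-of-vocabulary words receive a floor
probability (default `1/(10 · total count)`) so scores stay finite. No
stemming is applied; matching stays deterministic.

Annotation is a greedy cover: candidate matches are accepted in descending
rank order (ties: longer match, lexicographic string, leftmost position)
when their score reaches `min_score` (default 0.2, exposed as a parameter)
and none of their token positions is already covered. The all-uncovered rule
is slightly stricter than "covers at least one new position" but it is what
guarantees that no token position is annotated twice — and non-overlapping
spans are exactly what the inline-XML writer requires. An accepted match
carries *every* concept having that string as a variant; ambiguity is
resolved later, with document-level evidence, not at match time.

## Facts by graph regularization

Per document, the distinct annotated concepts form an affinity matrix

$$M = M_{isa} + M_{anc} + M_R + M_{sents}$$

with unit entries for proper subsumption and for named relations, a shared
proper-ancestor count scaled by `1/γ` (γ defaults to the maximum taxonomy
depth, the natural scale for ancestor counts), and unit entries for
sentence co-occurrence — suppressed when the two concepts are *in conflict*,
i.e. candidates of the same ambiguous annotation. The diagonal is forced to
zero: self-affinity would distort the normalization below.

Ranking solves the regularization problem in closed form:

$$R = (1-\alpha)\,(I - \alpha S)^{-1} Y, \qquad
S = D^{-1/2} M D^{-1/2}$$

with `D` the degree matrix (isolated concepts get zero rows, hence keep rank
`(1-α)Y_i`) and α = 0.9 the shipped default. The closed form equals the
fixed point of `R ← αSR + (1-α)Y`; the test suite verifies agreement to
1e−8 on random instances, and `α = 0` returns `Y` unchanged.

**Disambiguation** iterates over ambiguous annotations in document order
(the order is otherwise unspecified; fixing it makes runs reproducible).
For an ambiguous candidate set A, `Y` is 0 on A and 1 elsewhere; after
propagation, members of A scoring strictly below the maximum *within A* are
rejected and deleted from the matrix and from every annotation. The
A-local maximum is the only coherent reading: every member of A starts at
`Y = 0`, so comparing against the global maximum would reject all of A.
Ties keep all tied members. Each rejecting pass strictly shrinks the
concept set, so the loop terminates and is idempotent at its fixed point.

**Fact building** re-propagates with `Y` = per-concept mention frequencies
(raw post-disambiguation counts) and assigns, per dimension, the top-ranked
concept present in the document (ties: higher frequency, then lexicographic
id — a fixed total order so results never depend on storage order).
Collection-level relevance of a concept aggregates (`sum` or `avg`) a score
(`hits` = exact fact count, or summed rank) over its reflexive descendants
within the dimension.

## Bridges

For two levels of different dimensions, the contingency cube counts, per
concept pair, the documents whose facts fall at-or-below both concepts
(reflexive `≼` roll-up), with marginals counted the same way against the
full collection size N. The 2×2 table is
`(n_ij, n_j − n_ij; n_i − n_ij, N − n_i − n_j + n_ij)` — the joint-absence
cell carries the `+ n_ij` correction so the table sums to N. Measures:
confidence, interest factor (lift; exactly 1 under independence), F1,
cohesion (Jaccard `n_ij/(n_i + n_j − n_ij)` — the standard association-
mining reading of "cohesion"), log-likelihood ratio and mutual information.
Bridges are cells whose score strictly exceeds δ with support ≥
`min_support` (default 2); *δ-maximum interesting pairs* keep a cell when
its best score across a battery of measures passes δ, labeled with the
maximizing measure.

Null-handling convention: cells with an empty marginal score 0, and N is
always the full collection size (documents with a null fact in either
dimension simply fall into the absence cells).

## Map operations

The conceptual map is a stack of layers (one per dimension level) with
visible concept sets and bridges between adjacent layers. Operations are
pure state transforms: `drill_down` replaces a concept by its direct
children (successors in the transitive reduction of the
dimension-restricted order, so a multi-path grandchild appears once);
`contains_keywords` tests whether any reflexive descendant's lexical
variant matches every query token; `drill_through_concept` ranks supporting
documents by `R^d` of the assigned concept (descendants contribute through
`≼`, consistent with cube counting); `drill_through_bridge` scores by the
product of the two endpoint relevances; `prune_state` removes a concept (or
everything but it) together with its bridges, with no recomputation.

## The synthetic study conditions

The generator is first-class, tested code; its defaults are the fixed study
conditions, not tuning knobs:

* 60 concepts in 3 disjoint single-rooted dimensions, depth ≤ 4, branching
  2–4, 15% chance of a second parent (a proper DAG, exercising multi-interval
  labels);
* one unique 2-token variant per concept plus ambiguous 2-token strings
  shared by two concepts of *different* dimensions at `ambiguity_rate`
  (default 0.2);
* a 400-word Zipfian filler/background vocabulary (exponent 1.1) disjoint
  from the lexicon vocabulary, so precision loss can come only from planted
  ambiguity;
* each document mentions at most one concept per dimension, one sentence
  per mention with filler words around the variant;
* an ambiguous variant is accompanied, in the same sentence, by the unique
  variant of the intended sense's parent, giving the intended sense affinity
  support while the decoy stays isolated — disambiguation is solvable by
  construction, and the intended sense is recorded in the planted truth;
* planted pairs co-occur with probability `lift · p²` (p = 0.1 marginal),
  keeping marginals at p so the realized interest factor targets the lift;
  infeasible lifts (`lift > 1/p`) are rejected with the feasible maximum;
  ambiguous variants are kept out of pair-driven dimensions so association
  recovery is not confounded with sense errors.

What passing tests on this material do *not* show: robustness to real
biomedical language (no abbreviations, coordination, spelling variation,
or lexicon gaps), to overlapping semantic-type systems, or to corpora whose
background distribution diverges from the annotation domain. The generator
isolates the algorithms; it does not imitate MeSH/UMLS scale or structure.

Test and acceptance problem sizes — 50 random DAGs up to 200 nodes for the
index oracle, 100 random propagation instances, corpora of 120–500
documents — were chosen as the smallest sizes at which every property is
exercised with comfortable statistical margins.

## Numerical choices and degenerate inputs

* The propagation solve uses a dense LU (`solve`); `I − αS` is safely
  invertible for α < 1 since the spectral radius of S is ≤ 1; a failed
  solve raises with the condition number.
* Zero-information strings (`idf(S) = 0`) score 0 rather than dividing by
  zero; empty bags have information 0.
* Empty documents, empty annotation sets, single-concept documents (1×1
  zero affinity matrix) and dimensions with no annotated concept (null
  fact entries) are all defined, tested paths.
* All tie-breaks are lexicographic after score and frequency, everywhere.

## Known limitations

* The is-a graph must be a DAG; cycles are rejected at load with the
  offending edges.
* `extract_fragment` with ancestors retained never needs contraction edges;
  the signature-only mode adds closest-retained-ancestor edges, which can
  densify very sparse signatures.
* Interval-index construction traverses the graph (queries do not); for
  taxonomies far beyond 10⁵ concepts a streaming build would be needed.
* The annotator's fallback for non-contiguous partial matches spans from
  the first to the last matched token, which can include intervening
  tokens in the reported character span.
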