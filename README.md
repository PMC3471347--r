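# semcube

Builds browsable **multidimensional semantic spaces** from annotated text
collections. `semcube` is for anyone who wants to analyze a document
collection through the lens of a concept taxonomy (a UMLS-style thesaurus:
concepts, semantic types, lexical variants, is-a hierarchy): it annotates
text by dictionary lookup, reduces each document to a *fact* with at most
one concept per semantic dimension, and mines cross-dimension associations
("semantic bridges") from contingency cubes over the fact table — the
back-end of an OLAP-style conceptual-map browser, with every operation
exposed as a data-returning R function.

## The method in brief

* **Interval index.** Taxonomic subsumption `a ≼ b` is answered by interval
  containment over post-order labels: each concept carries a set of
  descendant (L−) and ancestor (L+) intervals; `a ≼ b` iff a's descendant
  intervals lie inside b's, and common ancestors come from intersecting L+
  sets. No graph traversal at query time.
* **Schema.** The taxonomy fragment is partitioned into disjoint dimensions
  by semantic-type/root selectors with priorities, and each dimension is
  stratified into antichain levels by longest-path depth, giving
  summarizable OLAP hierarchies.
* **Annotation.** Lexicon strings S are ranked against sentence chunks T by
  `rank(S,T) = [(idf(S) − idf(S∖T)) / idf(S)] · |S∩T| / ambiguity(S)`,
  with idf the information content under a background word model; a greedy
  cover accepts non-overlapping top-ranked matches, keeping all candidate
  senses of ambiguous strings.
* **Facts.** Per document, concepts form an affinity matrix
  `M = M_isa + M_anc + M_R + M_sents`; ranking solves the regularization
  problem `R = (1−α)(I−αS)⁻¹Y` over the Laplacian-normalized
  `S = D^{−1/2} M D^{−1/2}` (α = 0.9). Ambiguous senses scoring below their
  alternatives are iteratively rejected; the surviving top-ranked concept
  per dimension becomes the fact.
* **Bridges.** For two levels of different dimensions, cube cells count
  documents whose facts fall at-or-below both concepts (reflexive ≼
  roll-up); 2×2 contingency tables yield confidence, interest factor
  (lift), F1, cohesion, log-likelihood ratio and mutual information;
  δ-maximum interesting pairs keep cells whose best measure beats δ.
* **Map engine + synthetic fixtures.** Drill-down / contains / drill-through
  / prune as pure state operations, and a seeded generator of taxonomies,
  lexicons, backgrounds and corpora with planted senses and planted
  associations, so the whole pipeline is testable offline.

## Worked example

```r
library(semcube)

cfg <- synth_config(seed = 42, n_docs = 200, ambiguity_rate = 0.2,
                    planted_pairs = data.frame(a = NA_character_,
                                               b = NA_character_, lift = 5))
syn    <- generate_ontology(cfg)          # taxonomy + lexicon + background
index  <- build_interval_index(syn$ontology)
schema <- build_schema(syn$ontology, syn$specs, index)
corpus <- generate_corpus(syn)            # documents + planted truth

res <- normalize_corpus(corpus$docs, syn$ontology, schema,
                        syn$background, index)
res$store
#> <semcube_fact_store> 200 facts over 3 dimension(s)

disambiguation_accuracy(res$annotations, corpus$truth)
#> accuracy 0.955 over 44 planted ambiguous mentions

pc <- corpus$truth$pair_counts            # the planted association
lv <- function(dim, cid)
  Filter(function(l) cid %in% l$members, schema$levels[[dim]])[[1]]
cube <- build_cube(res$store,
                   lv(dimension_of(schema, pc$a), pc$a),
                   lv(dimension_of(schema, pc$b), pc$b), index)
max_interesting_pairs(cube, c("interest_factor", "conf"), delta = 2)
#>     c_i   c_j         measure    score support n_i n_j   N
#> 1 C0020 C0036 interest_factor 5.291005      10  21  18 200
```

The one surviving δ-maximum pair is exactly the planted association
(C0020/C0036, planted at lift 5, recovered at interest factor 5.29 — i.e.
the pair co-occurs 5.3× more often than independence predicts, supported by
10 documents); 95.5% of planted ambiguous mentions were resolved to their
intended sense by the regularization loop.

A command-line interface over the same functions ships at
`inst/cli/semcube.R` (subcommands `synth`, `schema`, `annotate`, `facts`,
`bridges`, `eval`; see its header for flags). The methods vignette
(`vignettes/methods.Rmd`) documents the model, parameter defaults and
design choices in detail.

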