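# Fixtures and independent oracles shared across tests.

# Random DAG ontology: edges always point from a higher to a lower id index,
# so acyclicity holds by construction. Independent of the synth module.
rand_dag_ontology <- function(n, seed, edge_factor = 2L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  if (n == 1L) {
    return(ontology(data.frame(id = ids, label = ids, semantic_types = "",
                               source = "X", stringsAsFactors = FALSE)))
  }
  ne <- edge_factor * n
  ch <- sample(2:n, ne, replace = TRUE)
  pa <- vapply(ch, function(i) sample.int(i - 1L, 1L), integer(1))
  edges <- unique(data.frame(child_id = ids[ch], parent_id = ids[pa],
                             stringsAsFactors = FALSE))
  ontology(data.frame(id = ids, label = ids, semantic_types = "",
                      source = "X", stringsAsFactors = FALSE),
           edges)
}

# Transitive-closure oracle by graph traversal (reflexive): m[a, b] iff a ≼ b.
closure_oracle <- function(onto) {
  ids <- sort(onto$concepts$id)
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(onto$isa_edges) > 0L) {
    g <- igraph::add_edges(g, rbind(onto$isa_edges$child_id,
                                    onto$isa_edges$parent_id))
  }
  d <- igraph::distances(g, v = ids, to = ids, mode = "out")
  is.finite(d)
}

# Small fixed taxonomy used across modules:
#
#   root
#   /  \
#  a    b        (a, b children of root)
#  |   / \
#  a1 b1 b2      (a1 child of a; b1, b2 children of b)
#  |
#  a2            (a2 child of a1)
toy_ontology <- function(types = NULL, lexicon = NULL, relations = NULL) {
  ids <- c("root", "a", "b", "a1", "b1", "b2", "a2")
  if (is.null(types)) types <- stats::setNames(rep("", 7), ids)
  concepts <- data.frame(id = ids, label = paste("the", ids),
                         semantic_types = unname(types[ids]), source = "TOY",
                         stringsAsFactors = FALSE)
  isa <- data.frame(
    child_id = c("a", "b", "a1", "b1", "b2", "a2"),
    parent_id = c("root", "root", "a", "b", "b", "a1"),
    stringsAsFactors = FALSE)
  ontology(concepts, isa,
           relations = if (is.null(relations)) empty_relations() else relations,
           lexicon = if (is.null(lexicon)) empty_lexicon() else lexicon)
}

# Uniform background over a tiny vocabulary; every word prob 0.01.
toy_background <- function() {
  words <- c(letters, paste0("w", 1:74))
  background_model(stats::setNames(rep(10, 100), words))
}

# P/R/F oracle by explicit double loops over igraph reachability.
prf_oracle <- function(system, gold, onto) {
  cl <- closure_oracle(onto)
  aligned <- function(x, y) cl[x, y] || cl[y, x]
  tp_p <- 0; n_s <- 0; tp_r <- 0; n_g <- 0
  for (d in union(names(system), names(gold))) {
    s <- unique(system[[d]]); g <- unique(gold[[d]])
    n_s <- n_s + length(s); n_g <- n_g + length(g)
    for (x in s) if (length(g) && any(sapply(g, aligned, x = x))) tp_p <- tp_p + 1
    for (y in g) if (length(s) && any(sapply(s, function(x) aligned(x, y)))) tp_r <- tp_r + 1
  }
  p <- if (n_s) tp_p / n_s else 0
  r <- if (n_g) tp_r / n_g else 0
  list(precision = p, recall = r,
       f_score = if (p + r > 0) 2 * p * r / (p + r) else 0)
}
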