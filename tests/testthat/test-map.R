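map_fixture <- function(n_docs = 30, seed = 2) {
  types <- c(root = "", a = "T1", a1 = "T1", a2 = "T1",
             b = "T2", b1 = "T2", b2 = "T2")
  lex <- data.frame(
    concept_id = c("a", "a1", "a2", "b", "b1", "b2"),
    surface_string = c("alpha", "alpha one", "alpha two", "beta",
                       "beta one", "beta two"),
    stringsAsFactors = FALSE)
  onto <- toy_ontology(types = types, lexicon = lex)
  idx <- build_interval_index(onto)
  sch <- build_schema(onto, list(dimension_spec("DA", 1, semantic_types = "T1"),
                                 dimension_spec("DB", 2, semantic_types = "T2")),
                      idx)
  set.seed(seed)
  facts <- lapply(seq_len(n_docs), function(i) {
    ca <- sample(c("a", "a1", "a2"), 1)
    cb <- sample(c(NA, "b", "b1", "b2"), 1)
    rv <- stats::setNames(stats::runif(2), c(ca, cb))
    rv <- rv[!is.na(names(rv))]
    structure(list(doc_id = sprintf("d%03d", i),
                   assignment = c(DA = ca, DB = cb),
                   rank_vector = rv,
                   concept_frequencies = rv * 0 + 1),
              class = "semcube_fact")
  })
  store <- fact_store(facts, sch)
  state <- map_state(sch, data.frame(dimension = c("DA", "DB"),
                                     depth = c(0L, 0L),
                                     stringsAsFactors = FALSE))
  list(onto = onto, idx = idx, sch = sch, store = store, state = state)
}

test_that("drill-down exposes direct children and handles leaves", {
  fx <- map_fixture()
  res <- drill_down(fx$state, "DA", "a", fx$idx)
  expect_equal(res$children, "a1")
  expect_false("a" %in% res$state$visible[["DA:0"]])
  expect_true("a1" %in% res$state$visible[["DA:0"]])
  # leaf: empty delta, state unchanged
  res2 <- drill_down(res$state, "DA", "a1", fx$idx)
  res3 <- drill_down(res2$state, "DA", "a2", fx$idx)
  expect_length(res3$children, 0)
  expect_identical(res3$state$visible, res2$state$visible)
})

test_that("diamond DAGs expose a multi-path grandchild exactly once", {
  # g reachable from r through both m1 and m2: children of r are m1, m2
  # (transitive reduction), and g appears only when a parent is expanded
  onto <- ontology(
    data.frame(id = c("r", "m1", "m2", "g"), label = "",
               semantic_types = "T1", source = "", stringsAsFactors = FALSE),
    data.frame(child_id = c("m1", "m2", "g", "g", "g"),
               parent_id = c("r", "r", "m1", "m2", "r"),
               stringsAsFactors = FALSE))
  idx <- build_interval_index(onto)
  sch <- build_schema(onto, list(dimension_spec("D", 1,
                                                semantic_types = "T1")), idx)
  kids <- dimension_children(sch, "D", "r", idx)
  expect_setequal(kids, c("m1", "m2"))  # direct edge r->g is transitive
  expect_equal(dimension_children(sch, "D", "m1", idx), "g")
})

test_that("contains matches keywords against descendant lexicons", {
  fx <- map_fixture()
  expect_true(contains_keywords(fx$sch, "DA", "a", "alpha", fx$onto, fx$idx))
  expect_true(contains_keywords(fx$sch, "DA", "a", "alpha two", fx$onto,
                                fx$idx))
  expect_false(contains_keywords(fx$sch, "DB", "b", "alpha", fx$onto,
                                 fx$idx))
  expect_error(contains_keywords(fx$sch, "DA", "a", "  ", fx$onto, fx$idx),
               "empty")
  # agreement with an exhaustive descendant scan
  cl <- closure_oracle(fx$onto)
  for (cid in c("a", "b", "a1")) {
    for (kw in c("alpha", "beta one", "gamma")) {
      dim <- if (cid %in% fx$sch$dimensions$DA) "DA" else "DB"
      desc <- intersect(rownames(cl)[cl[, cid]], fx$sch$dimensions[[dim]])
      lex <- fx$onto$lexicon
      want <- any(vapply(lex$surface_string[lex$concept_id %in% desc],
                         function(s) all(tokenize(kw)$tokens %in%
                                           tokenize(s)$tokens),
                         logical(1)))
      expect_identical(
        contains_keywords(fx$sch, dim, cid, kw, fx$onto, fx$idx), want)
    }
  }
})

test_that("concept drill-through ranks supporting documents by rank score", {
  fx <- map_fixture()
  ranked <- drill_through_concept(fx$store, "a", fx$idx)
  # oracle: every document assigns some DA concept (all ≼ a), sorted by score
  want <- do.call(rbind, lapply(fx$store$facts, function(f) {
    data.frame(doc_id = f$doc_id,
               score = unname(f$rank_vector[f$assignment["DA"]]),
               stringsAsFactors = FALSE)
  }))
  want <- want[order(-want$score, want$doc_id), ]
  expect_equal(ranked$doc_id, want$doc_id)
  expect_equal(ranked$score, want$score)
  expect_true(all(diff(ranked$score) <= 1e-12))
  # concept with no support: empty result
  none <- drill_through_concept(
    fx$store, "b2", fx$idx)
  sup <- vapply(fx$store$facts, function(f)
    !is.na(f$assignment["DB"]) && f$assignment["DB"] == "b2", logical(1))
  expect_equal(nrow(none), sum(sup))
})

test_that("bridge drill-through scores by the product of relevances", {
  fx <- map_fixture()
  bridge <- data.frame(c_i = "a", c_j = "b", stringsAsFactors = FALSE)
  ranked <- drill_through_bridge(fx$store, bridge, fx$idx)
  want <- list()
  for (f in fx$store$facts) {
    if (is.na(f$assignment["DB"])) next  # one-sided support is excluded
    want[[length(want) + 1L]] <- data.frame(
      doc_id = f$doc_id,
      score = unname(f$rank_vector[f$assignment["DA"]]) *
        unname(f$rank_vector[f$assignment["DB"]]),
      stringsAsFactors = FALSE)
  }
  want <- do.call(rbind, want)
  want <- want[order(-want$score, want$doc_id), ]
  expect_equal(ranked$doc_id, want$doc_id)
  expect_equal(ranked$score, want$score)
})

test_that("prune operations remove concepts and their bridges only", {
  fx <- map_fixture()
  st <- fx$state
  st$bridges <- data.frame(c_i = c("a", "a"), c_j = c("b", "b1"),
                           measure = "conf", score = c(0.5, 0.4),
                           support = c(3L, 2L), n_i = 5L, n_j = 4L, N = 30L,
                           stringsAsFactors = FALSE)
  st$visible[["DB:0"]] <- c("b", "b1")
  rm_state <- prune_state(st, "DB", "b", mode = "removal")
  expect_false("b" %in% rm_state$visible[["DB:0"]])
  expect_false(any(rm_state$bridges$c_i == "b" | rm_state$bridges$c_j == "b"))
  expect_true(any(rm_state$bridges$c_j == "b1"))

  sel_state <- prune_state(st, "DB", "b", mode = "selection")
  expect_equal(sel_state$visible[["DB:0"]], "b")
  expect_false(any(sel_state$bridges$c_j == "b1"))
  # selection on a single-concept layer is the identity
  sel2 <- prune_state(sel_state, "DB", "b", mode = "selection")
  expect_identical(sel2$visible, sel_state$visible)
})

test_that("map state invariants survive random operation sequences", {
  fx <- map_fixture()
  set.seed(33)
  state <- fx$state
  for (step in 1:40) {
    op <- sample(c("drill", "prune_rm", "prune_sel"), 1)
    dim <- sample(c("DA", "DB"), 1)
    key <- paste0(dim, ":0")
    vis <- setdiff(state$visible[[key]], character(0))
    if (length(vis) == 0L) next
    cid <- sample(vis, 1)
    state <- switch(op,
      drill = drill_down(state, dim, cid, fx$idx, store = fx$store,
                         measure = "conf", delta = 0.1,
                         min_support = 1)$state,
      prune_rm = prune_state(state, dim, cid, "removal"),
      prune_sel = prune_state(state, dim, cid, "selection"))
    # invariants: visible sets stay inside their dimension and disjoint;
    # bridge endpoints stay visible
    expect_true(all(state$visible[["DA:0"]] %in% fx$sch$dimensions$DA))
    expect_true(all(state$visible[["DB:0"]] %in% fx$sch$dimensions$DB))
    if (nrow(state$bridges) > 0) {
      expect_true(all(state$bridges$c_i %in% unlist(state$visible)))
      expect_true(all(state$bridges$c_j %in% unlist(state$visible)))
    }
  }
})

test_that("drill-down is reversible at the state level", {
  fx <- map_fixture()
  before <- fx$state$visible[["DA:0"]]
  res <- drill_down(fx$state, "DA", "a", fx$idx)
  st <- res$state
  st$visible[["DA:0"]] <- sort(c(setdiff(st$visible[["DA:0"]], res$children),
                                 "a"))
  expect_identical(st$visible[["DA:0"]], sort(before))
})
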