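# chain taxonomy y <- x <- parent <- child gives the child/parent pair two
# proper shared ancestors (x and y)
chain_ontology <- function() {
  ontology(
    data.frame(id = c("y", "x", "parent", "child"), label = "",
               semantic_types = "T1", source = "", stringsAsFactors = FALSE),
    data.frame(child_id = c("x", "parent", "child"),
               parent_id = c("y", "x", "parent"), stringsAsFactors = FALSE))
}

ann_row <- function(doc, cands, sentence, start = 0L) {
  df <- data.frame(doc_id = doc, start = start, end = start + 1L,
                   string = paste(cands, collapse = "|"), score = 1,
                   sentence = sentence, ambiguous = length(cands) > 1,
                   stringsAsFactors = FALSE)
  df$candidates <- list(cands)
  df
}

test_that("affinity matrix combines the four components as specified", {
  onto <- chain_ontology()
  idx <- build_interval_index(onto)
  # parent and child co-annotated in different sentences, gamma = 4:
  # isa = 1, anc = |{x, y}| / 4 = 0.5, rel = 0, sents = 0 -> 1.5
  ann <- rbind(ann_row("d", "child", 1, 0L), ann_row("d", "parent", 2, 10L))
  M <- build_affinity_matrix(ann, onto, idx, gamma = 4)
  expect_equal(M$M["child", "parent"], 1.5)
  expect_equal(M$M["parent", "child"], 1.5)
  expect_equal(diag(M$M), c(child = 0, parent = 0))
  expect_equal(M$components$isa["child", "parent"], 1)
  expect_equal(M$components$anc["child", "parent"], 0.5)

  # single-concept document: 1x1 zero matrix
  M1 <- build_affinity_matrix(ann_row("d", "child", 1), onto, idx, gamma = 4)
  expect_equal(unname(M1$M), matrix(0, 1, 1))
})

test_that("conflicting candidates get no sentence affinity", {
  onto <- ontology(
    data.frame(id = c("p", "q"), label = "", semantic_types = "",
               source = "", stringsAsFactors = FALSE))
  idx <- build_interval_index(onto)
  # p and q are candidates of one ambiguous annotation in one sentence:
  # unrelated taxonomically, so every component must vanish
  ann <- ann_row("d", c("p", "q"), 1)
  M <- build_affinity_matrix(ann, onto, idx, gamma = 1)
  expect_equal(unname(M$M), matrix(0, 2, 2))
})

test_that("named relations contribute symmetric affinity", {
  onto <- ontology(
    data.frame(id = c("p", "q"), label = "", semantic_types = "",
               source = "", stringsAsFactors = FALSE),
    relations = data.frame(relation_name = "treats", source_id = "p",
                           target_id = "q", stringsAsFactors = FALSE))
  idx <- build_interval_index(onto)
  ann <- rbind(ann_row("d", "p", 1), ann_row("d", "q", 2, 10L))
  M <- build_affinity_matrix(ann, onto, idx, gamma = 1)
  expect_equal(M$M["p", "q"], 1)
  expect_equal(M$M["q", "p"], 1)
})

test_that("propagation solves the regularization closed form", {
  # alpha = 0 is the identity on Y
  M <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  pr0 <- propagate(M, c(1, 0), alpha = 0)
  expect_equal(unname(pr0$R), c(1, 0))
  # hand-inverted 2x2: R = (10/19, 9/19)
  pr <- propagate(M, c(1, 0), alpha = 0.9)
  expect_equal(unname(pr$R), c(10 / 19, 9 / 19), tolerance = 1e-12)
  # zero matrix: R = (1 - alpha) Y, the isolated-concept rank
  Z <- matrix(0, 2, 2, dimnames = dimnames(M))
  expect_equal(unname(propagate(Z, c(2, 3), alpha = 0.9)$R),
               0.1 * c(2, 3), tolerance = 1e-12)
  expect_error(propagate(M, c(1, 0), alpha = 1), "alpha")
  expect_error(propagate(M, c(1, 0), alpha = -0.1), "alpha")
})

test_that("closed form equals fixed-point iteration on random instances", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    A <- matrix(stats::runif(n * n), n, n) * (stats::runif(n * n) < 0.5)
    M <- A + t(A); diag(M) <- 0
    dimnames(M) <- list(paste0("c", 1:n), paste0("c", 1:n))
    Y <- stats::runif(n)
    alpha <- stats::runif(1, 0, 0.95)
    pr <- propagate(M, Y, alpha)
    R_it <- Y
    for (i in 1:500) R_it <- alpha * (pr$S %*% R_it) + (1 - alpha) * Y
    expect_equal(unname(pr$R), as.numeric(R_it), tolerance = 1e-8)
  }
})

test_that("disambiguation keeps the affinity-supported sense", {
  # X (intended) is linked to context concept U; decoy D is isolated
  onto <- ontology(
    data.frame(id = c("U", "X", "D"), label = "", semantic_types = "",
               source = "", stringsAsFactors = FALSE),
    data.frame(child_id = "X", parent_id = "U", stringsAsFactors = FALSE))
  idx <- build_interval_index(onto)
  ann <- rbind(ann_row("d", c("D", "X"), 1), ann_row("d", "U", 1, 10L))
  M <- build_affinity_matrix(ann, onto, idx, gamma = 1)
  # hand check of Eq-style propagation: Y = (1,0,0) over (U, X, D); X gets
  # mass through its edge to U, D stays at (1-alpha)*0 = 0
  pr <- propagate(M, c(1, 0, 0)[match(M$concepts, c("U", "X", "D"))], 0.9)
  expect_gt(pr$R["X"], pr$R["D"])
  dis <- disambiguate(ann, M, alpha = 0.9)
  expect_equal(dis$rejected$concept, "D")
  expect_equal(dis$annotations$candidates[[1]], "X")
  expect_false(any(dis$annotations$ambiguous))
  # idempotent at the fixed point
  dis2 <- disambiguate(dis$annotations, dis$M, alpha = 0.9)
  expect_equal(nrow(dis2$rejected), 0)
})

test_that("symmetric ambiguity keeps both candidates (tie rule)", {
  onto <- ontology(
    data.frame(id = c("p", "q"), label = "", semantic_types = "",
               source = "", stringsAsFactors = FALSE))
  idx <- build_interval_index(onto)
  ann <- ann_row("d", c("p", "q"), 1)
  M <- build_affinity_matrix(ann, onto, idx, gamma = 1)
  dis <- disambiguate(ann, M, alpha = 0.9)
  expect_equal(nrow(dis$rejected), 0)
  expect_setequal(dis$annotations$candidates[[1]], c("p", "q"))
})

fact_fixture_schema <- function(onto, idx) {
  build_schema(onto, list(dimension_spec("D1", 1, semantic_types = "T1")),
               idx)
}

test_that("facts assign the top-ranked concept per dimension", {
  onto <- chain_ontology()
  idx <- build_interval_index(onto)
  sch <- fact_fixture_schema(onto, idx)
  # child mentioned 3 times, parent once, identical affinities otherwise:
  # the frequent concept wins by monotonicity of the propagation in Y
  ann <- rbind(ann_row("d", "child", 1, 0L), ann_row("d", "child", 2, 10L),
               ann_row("d", "child", 3, 20L), ann_row("d", "parent", 4, 30L))
  M <- build_affinity_matrix(ann, onto, idx, gamma = 4)
  fact <- build_fact(ann, M, sch, alpha = 0.9, doc_id = "d")
  expect_equal(unname(fact$assignment["D1"]), "child")
  expect_equal(unname(fact$concept_frequencies["child"]), 3)

  # dimension with no annotated concept stays null
  sch2 <- build_schema(
    toy_ontology(types = c(root = "", a = "T1", a1 = "T1", a2 = "T1",
                           b = "T2", b1 = "T2", b2 = "T2")),
    list(dimension_spec("DA", 1, semantic_types = "T1"),
         dimension_spec("DB", 2, semantic_types = "T2")))
  onto2 <- toy_ontology()
  idx2 <- build_interval_index(onto2)
  ann2 <- ann_row("d", "a1", 1)
  M2 <- build_affinity_matrix(ann2, onto2, idx2, gamma = 2)
  fact2 <- build_fact(ann2, M2, sch2, doc_id = "d")
  expect_equal(unname(fact2$assignment["DA"]), "a1")
  expect_true(is.na(fact2$assignment["DB"]))
})

test_that("concept relevance rolls hits up the taxonomy", {
  onto <- toy_ontology(types = stats::setNames(rep("T1", 7),
                                               c("root", "a", "b", "a1",
                                                 "b1", "b2", "a2")))
  idx <- build_interval_index(onto)
  sch <- fact_fixture_schema(onto, idx)
  mk_fact <- function(doc, cid) {
    structure(list(doc_id = doc,
                   assignment = c(D1 = cid),
                   rank_vector = stats::setNames(0.5, cid),
                   concept_frequencies = stats::setNames(1, cid)),
              class = "semcube_fact")
  }
  # b has children b1 (2 hits) and b2 (3 hits) and 1 own hit -> sum 6
  facts <- c(lapply(sprintf("x%d", 1:2), mk_fact, cid = "b1"),
             lapply(sprintf("y%d", 1:3), mk_fact, cid = "b2"),
             list(mk_fact("z1", "b")))
  store <- fact_store(facts, sch)
  expect_equal(concept_relevance(store, "b", "D1", "sum", "hits", idx), 6)
  expect_equal(concept_relevance(store, "b1", "D1", "sum", "hits", idx), 2)
  expect_equal(concept_relevance(store, "a2", "D1", "sum", "hits", idx), 0)
  # rank mode sums the stored rank of assigned docs
  expect_equal(concept_relevance(store, "b", "D1", "sum", "rank", idx), 3)
  expect_error(concept_relevance(store, "ghost", "D1", "sum", "hits", idx),
               "ghost")
})

test_that("gold evaluation matches the alignment semantics and the oracle", {
  onto <- toy_ontology()
  idx <- build_interval_index(onto)
  gold <- list(d1 = c("a", "b1"), d2 = "b")
  # identical sets: perfect scores
  r <- evaluate_against_gold(gold, gold, idx)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f_score, 1)
  # system outputs strict descendants of gold: recall stays 1
  sys_desc <- list(d1 = c("a1", "b1"), d2 = "b2")
  r2 <- evaluate_against_gold(sys_desc, gold, idx)
  expect_equal(r2$recall, 1)
  # randomized sets agree with the traversal-based oracle
  ids <- concept_ids(onto)
  set.seed(17)
  for (k in 1:10) {
    system <- lapply(1:3, function(i) sample(ids, sample(1:3, 1)))
    gd <- lapply(1:3, function(i) sample(ids, sample(1:3, 1)))
    names(system) <- names(gd) <- paste0("d", 1:3)
    got <- evaluate_against_gold(system, gd, idx)
    want <- prf_oracle(system, gd, onto)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(evaluate_against_gold(gold, list(), idx), "empty gold")
})
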