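cell <- function(n_ij, n_i, n_j, N) {
  data.frame(n_ij = n_ij, n_i = n_i, n_j = n_j, N = N)
}

test_that("contingency table uses the overlap-corrected fourth cell", {
  m <- contingency(cell(2, 4, 5, 20))
  expect_equal(as.numeric(t(m)), c(2, 3, 2, 13))
  expect_equal(sum(m), 20)
  # degenerate full co-occurrence
  m2 <- contingency(cell(7, 7, 7, 7))
  expect_equal(as.numeric(m2), c(7, 0, 0, 0))
  # disjoint supports
  m3 <- contingency(cell(0, 4, 5, 20))
  expect_equal(as.numeric(t(m3)), c(0, 5, 4, 11))
  expect_error(contingency(cell(5, 4, 5, 20)), "invalid")
})

test_that("bridge measures match hand arithmetic and identities", {
  cl <- cell(2, 4, 5, 20)
  expect_equal(score_bridge(cl, "conf"), 0.5)
  expect_equal(score_bridge(cl, "f1"), 4 / 9)
  expect_equal(score_bridge(cl, "cohesion"), 2 / 7)
  expect_equal(score_bridge(cl, "interest_factor"), 2 * 20 / (4 * 5))
  # conf = 1 when the rule always fires
  expect_equal(score_bridge(cell(4, 4, 9, 20), "conf"), 1)
  # interest factor is exactly 1 under independence
  expect_equal(score_bridge(cell(2, 4, 10, 20), "interest_factor"), 1)
  # llr and mi against a generic 2x2 association oracle (entropy form)
  O <- contingency(cl)
  p <- O / sum(O)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  mi_oracle <- H(rowSums(p)) + H(colSums(p)) - H(as.numeric(p))
  expect_equal(score_bridge(cl, "mi"), mi_oracle, tolerance = 1e-12)
  expect_equal(score_bridge(cl, "llr"), 2 * sum(O) * mi_oracle,
               tolerance = 1e-12)
  # empty marginal scores 0 by convention
  expect_equal(score_bridge(cell(0, 0, 5, 20), "conf"), 0)
  expect_error(score_bridge(cl, "nope"), "unknown measure")
})

test_that("measure invariants hold on fuzzed cells", {
  set.seed(23)
  for (k in 1:200) {
    N <- sample(5:200, 1)
    n_i <- sample(1:N, 1); n_j <- sample(1:N, 1)
    lo <- max(0, n_i + n_j - N)
    hi <- min(n_i, n_j)
    n_ij <- if (lo == hi) lo else sample(lo:hi, 1)
    cl <- cell(n_ij, n_i, n_j, N)
    conf <- score_bridge(cl, "conf")
    f1 <- score_bridge(cl, "f1")
    coh <- score_bridge(cl, "cohesion")
    expect_gte(conf, 0); expect_lte(conf, 1)
    expect_gte(f1, 0); expect_lte(f1, 1)
    expect_lte(coh, f1 + 1e-12)
    expect_lte(coh, conf + 1e-12)
    expect_gte(score_bridge(cl, "llr"), -1e-9)
  }
})

# a toy fact store over two dimensions for cube tests
bridge_store <- function(n_docs = 40, seed = 1) {
  types <- c(root = "", a = "T1", a1 = "T1", a2 = "T1",
             b = "T2", b1 = "T2", b2 = "T2")
  onto <- toy_ontology(types = types)
  idx <- build_interval_index(onto)
  sch <- build_schema(onto, list(dimension_spec("DA", 1, semantic_types = "T1"),
                                 dimension_spec("DB", 2, semantic_types = "T2")),
                      idx)
  set.seed(seed)
  facts <- lapply(seq_len(n_docs), function(i) {
    ca <- sample(c(NA, "a", "a1", "a2"), 1)
    cb <- sample(c(NA, "b", "b1", "b2"), 1)
    rv <- stats::setNames(stats::runif(2), c(ca, cb))
    rv <- rv[!is.na(names(rv))]
    structure(list(doc_id = sprintf("d%03d", i),
                   assignment = c(DA = ca, DB = cb),
                   rank_vector = rv,
                   concept_frequencies = rv * 0 + 1),
              class = "semcube_fact")
  })
  list(store = fact_store(facts, sch), idx = idx, sch = sch, onto = onto)
}

test_that("cube cells equal a brute-force recount", {
  fx <- bridge_store(n_docs = 200, seed = 9)
  cl <- closure_oracle(fx$onto)
  for (la in fx$sch$levels$DA) {
    for (lb in fx$sch$levels$DB) {
      cube <- build_cube(fx$store, la, lb, fx$idx)
      for (ci in la$members) {
        for (cj in lb$members) {
          n_ij <- 0L; n_i <- 0L; n_j <- 0L
          for (f in fx$store$facts) {
            bi <- !is.na(f$assignment["DA"]) && cl[f$assignment["DA"], ci]
            bj <- !is.na(f$assignment["DB"]) && cl[f$assignment["DB"], cj]
            n_i <- n_i + bi; n_j <- n_j + bj; n_ij <- n_ij + (bi && bj)
          }
          row <- cube[cube$c_i == ci & cube$c_j == cj, ]
          if (n_ij == 0L) {
            expect_equal(nrow(row), 0)
          } else {
            expect_equal(row$n_ij, n_ij)
            expect_equal(row$n_i, n_i)
            expect_equal(row$n_j, n_j)
            expect_equal(row$N, 200)
          }
        }
      }
    }
  }
})

test_that("facts at descendants roll up into the cube counts", {
  fx <- bridge_store(n_docs = 30, seed = 4)
  top_a <- fx$sch$levels$DA[[1]]
  top_b <- fx$sch$levels$DB[[1]]
  cube <- build_cube(fx$store, top_a, top_b, fx$idx)
  both <- sum(vapply(fx$store$facts, function(f) {
    !is.na(f$assignment["DA"]) && !is.na(f$assignment["DB"])
  }, logical(1)))
  expect_equal(cube$n_ij[cube$c_i == "a" & cube$c_j == "b"], both)
  expect_error(build_cube(fx$store, top_a, fx$sch$levels$DA[[2]], fx$idx),
               "different dimensions")
})

test_that("find_bridges filters and sorts like the brute-force oracle", {
  fx <- bridge_store(n_docs = 60, seed = 12)
  la <- fx$sch$levels$DA[[2]]; lb <- fx$sch$levels$DB[[2]]
  cube <- build_cube(fx$store, la, lb, fx$idx)
  br <- find_bridges(cube, "conf", delta = 0.3, min_support = 2)
  # oracle: filter and sort by hand
  sc <- vapply(seq_len(nrow(cube)), function(i) cube$n_ij[i] / cube$n_i[i],
               numeric(1))
  keep <- which(sc > 0.3 & cube$n_ij >= 2)
  expect_equal(nrow(br), length(keep))
  expect_setequal(paste(br$c_i, br$c_j), paste(cube$c_i[keep], cube$c_j[keep]))
  expect_true(all(diff(br$score) <= 1e-12))
  # delta above every score: empty; delta = -Inf not allowed (finite),
  # a very low delta returns every supported cell
  expect_equal(nrow(find_bridges(cube, "conf", delta = 2)), 0)
  all_br <- find_bridges(cube, "conf", delta = -1, min_support = 1)
  expect_equal(nrow(all_br), nrow(cube))
})

test_that("delta-maximum pairs pick the maximizing measure per cell", {
  fx <- bridge_store(n_docs = 60, seed = 12)
  la <- fx$sch$levels$DA[[2]]; lb <- fx$sch$levels$DB[[2]]
  cube <- build_cube(fx$store, la, lb, fx$idx)
  # single measure reduces to find_bridges
  m1 <- max_interesting_pairs(cube, "conf", delta = 0.3, min_support = 2)
  f1 <- find_bridges(cube, "conf", delta = 0.3, min_support = 2)
  expect_equal(m1, f1)
  # per-cell exhaustive max oracle
  meas <- c("conf", "f1", "cohesion")
  mx <- max_interesting_pairs(cube, meas, delta = 0.25, min_support = 1)
  for (i in seq_len(nrow(cube))) {
    sc <- vapply(meas, function(m) score_bridge(cube[i, ], m), numeric(1))
    row <- mx[mx$c_i == cube$c_i[i] & mx$c_j == cube$c_j[i], ]
    if (max(sc) > 0.25) {
      expect_equal(row$score, unname(max(sc)))
      expect_equal(row$measure, meas[which.max(sc)])
    } else {
      expect_equal(nrow(row), 0)
    }
  }
})
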