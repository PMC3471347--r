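#' Build a contingency cube between two dimension levels
#'
#' For every concept pair (c_i, c_j) from two levels of *different*
#' dimensions, counts the documents whose fact falls at or below both
#' concepts under reflexive subsumption:
#' `n_ij = |{d : fact(d)[D_i] ≼ c_i  and  fact(d)[D_j] ≼ c_j}|`,
#' with marginals `n_i`, `n_j` rolled up the same way and `N` the full
#' collection size. Only cells with `n_ij > 0` are materialized.
#'
#' @param store A `semcube_fact_store`.
#' @param level_i,level_j Levels (as produced by [stratify_levels()]) from
#'   two different dimensions.
#' @param index Interval index covering both dimensions.
#' @return data.frame with columns `c_i`, `c_j`, `n_ij`, `n_i`, `n_j`, `N`,
#'   plus attributes `dim_i`, `dim_j`; class `semcube_cube`.
#' @export
build_cube <- function(store, level_i, level_j, index) {
  if (identical(level_i$dimension, level_j$dimension)) {
    stop("cube levels must come from different dimensions (i != j)")
  }
  di <- level_i$dimension; dj <- level_j$dimension
  ai <- vapply(store$facts, function(f) f$assignment[[di]], character(1))
  aj <- vapply(store$facts, function(f) f$assignment[[dj]], character(1))
  N <- store$n_col

  below <- function(assigned, c_up) {
    ok <- !is.na(assigned)
    ok[ok] <- vapply(assigned[ok], function(a) is_descendant(index, a, c_up),
                     logical(1))
    ok
  }
  bi <- lapply(level_i$members, function(ci) below(ai, ci))
  bj <- lapply(level_j$members, function(cj) below(aj, cj))
  names(bi) <- level_i$members
  names(bj) <- level_j$members
  rows <- list()
  for (ci in level_i$members) {
    for (cj in level_j$members) {
      nij <- sum(bi[[ci]] & bj[[cj]])
      if (nij > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          c_i = ci, c_j = cj, n_ij = nij,
          n_i = sum(bi[[ci]]), n_j = sum(bj[[cj]]), N = N,
          stringsAsFactors = FALSE)
      }
    }
  }
  cube <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(c_i = character(), c_j = character(), n_ij = integer(),
               n_i = integer(), n_j = integer(), N = integer(),
               stringsAsFactors = FALSE)
  attr(cube, "dim_i") <- di
  attr(cube, "dim_j") <- dj
  class(cube) <- c("semcube_cube", class(cube))
  cube
}

#' 2x2 contingency table of a cube cell
#'
#' Returns the table
#' `(n_ij, n_j - n_ij; n_i - n_ij, N - n_i - n_j + n_ij)` — joint presence,
#' each one-sided presence, and joint absence — which sums to N.
#'
#' @param cell One-row data.frame (or list) with `n_ij`, `n_i`, `n_j`, `N`.
#' @return 2x2 numeric matrix, rows = c_i present/absent, cols = c_j
#'   present/absent.
#' @export
contingency <- function(cell) {
  nij <- cell$n_ij; ni <- cell$n_i; nj <- cell$n_j; N <- cell$N
  if (nij < 0 || nij > min(ni, nj) || max(ni, nj) > N) {
    stop("invalid cube cell: need 0 <= n_ij <= min(n_i, n_j) <= N")
  }
  m <- matrix(c(nij, ni - nij, nj - nij, N - ni - nj + nij), 2, 2,
              dimnames = list(c_i = c("present", "absent"),
                              c_j = c("present", "absent")))
  if (any(m < 0)) stop("invalid cube cell: negative contingency count")
  m
}

#' Score a cube cell with an interestingness measure
#'
#' Measures over the 2x2 contingency table:
#' * `conf` — confidence of the rule c_i -> c_j, `n_ij / n_i`;
#' * `interest_factor` — lift, `n_ij * N / (n_i * n_j)`; 1 under exact
#'   independence;
#' * `f1` — `2 n_ij / (n_i + n_j)`;
#' * `cohesion` — Jaccard, `n_ij / (n_i + n_j - n_ij)`;
#' * `llr` — log-likelihood ratio `2 * sum O log(O/E)` with expected counts
#'   from the marginals (`0 log 0 = 0`);
#' * `mi` — mutual information of the empirical 2x2 joint, in nats.
#' Cells with an empty marginal score 0 by convention.
#'
#' @param cell One-row data.frame (or list) with `n_ij`, `n_i`, `n_j`, `N`.
#' @param measure One of `"conf"`, `"interest_factor"`, `"llr"`, `"mi"`,
#'   `"f1"`, `"cohesion"`.
#' @return Numeric scalar.
#' @export
score_bridge <- function(cell, measure) {
  measures <- c("conf", "interest_factor", "llr", "mi", "f1", "cohesion")
  if (!measure %in% measures) {
    stop("unknown measure '", measure, "'; use one of: ",
         paste(measures, collapse = ", "))
  }
  nij <- cell$n_ij; ni <- cell$n_i; nj <- cell$n_j; N <- cell$N
  if (ni == 0 || nj == 0) return(0)
  switch(measure,
    conf = nij / ni,
    interest_factor = nij * N / (ni * nj),
    f1 = 2 * nij / (ni + nj),
    cohesion = nij / (ni + nj - nij),
    llr = {
      O <- contingency(cell)
      E <- outer(rowSums(O), colSums(O)) / N
      terms <- ifelse(O > 0, O * log(O / E), 0)
      2 * sum(terms)
    },
    mi = {
      O <- contingency(cell)
      p <- O / N
      px <- rowSums(p); py <- colSums(p)
      terms <- ifelse(p > 0, p * log(p / outer(px, py)), 0)
      sum(terms)
    })
}

#' Extract bridges from a cube under one measure
#'
#' Bridges are the cells whose score strictly exceeds `delta` and whose
#' support `n_ij` reaches `min_support`, sorted by descending score then
#' lexicographic pair.
#'
#' @param cube A `semcube_cube`.
#' @param measure See [score_bridge()].
#' @param delta Score threshold (strict).
#' @param min_support Minimum joint support (default 2).
#' @return data.frame with `c_i`, `c_j`, `measure`, `score`, `support`,
#'   `n_i`, `n_j`, `N`.
#' @export
find_bridges <- function(cube, measure, delta, min_support = 2L) {
  stopifnot(is.finite(delta), min_support >= 1L)
  if (nrow(cube) == 0L) return(empty_bridges())
  score <- vapply(seq_len(nrow(cube)), function(i) {
    score_bridge(cube[i, ], measure)
  }, numeric(1))
  keep <- score > delta & cube$n_ij >= min_support
  if (!any(keep)) return(empty_bridges())
  out <- data.frame(c_i = cube$c_i[keep], c_j = cube$c_j[keep],
                    measure = rep(measure, sum(keep)), score = score[keep],
                    support = cube$n_ij[keep], n_i = cube$n_i[keep],
                    n_j = cube$n_j[keep], N = cube$N[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$c_i, out$c_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_bridges <- function() {
  data.frame(c_i = character(), c_j = character(), measure = character(),
             score = numeric(), support = integer(), n_i = integer(),
             n_j = integer(), N = integer(), stringsAsFactors = FALSE)
}

#' Delta-maximum interesting pairs over a battery of measures
#'
#' Scores every cell with each requested measure and keeps the cell when its
#' best score strictly exceeds `delta`; the emitted bridge is labeled with
#' the maximizing measure (ties resolved by the order the measures were
#' given).
#'
#' @param cube A `semcube_cube`.
#' @param measures Character vector of measures (>= 1; see
#'   [score_bridge()]).
#' @param delta Score threshold (strict).
#' @param min_support Minimum joint support (default 2).
#' @return data.frame as in [find_bridges()].
#' @export
max_interesting_pairs <- function(cube, measures, delta, min_support = 2L) {
  if (length(measures) == 0L) stop("need at least one measure")
  if (nrow(cube) == 0L) return(empty_bridges())
  rows <- list()
  for (i in seq_len(nrow(cube))) {
    sc <- vapply(measures, function(m) score_bridge(cube[i, ], m), numeric(1))
    best <- which.max(sc)  # first max = measure-name order
    if (sc[best] > delta && cube$n_ij[i] >= min_support) {
      rows[[length(rows) + 1L]] <- data.frame(
        c_i = cube$c_i[i], c_j = cube$c_j[i], measure = measures[best],
        score = unname(sc[best]), support = cube$n_ij[i],
        n_i = cube$n_i[i], n_j = cube$n_j[i], N = cube$N[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_bridges())
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$c_i, out$c_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
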