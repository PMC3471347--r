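#' Build an interval index over an ontology's taxonomy
#'
#' Encodes taxonomic reachability as sets of closed integer intervals so
#' subsumption becomes interval containment: each concept receives a
#' post-order label, and its descendant space (L-) is the coalesced interval
#' cover of the labels of all its reflexive descendants; its ancestor space
#' (L+) is the dual cover over reflexive ancestors. In a DAG a concept
#' reachable through several parents contributes a non-contiguous label to
#' its ancestors' sets, which is why each space is a *set* of intervals.
#' Once built, `a ≼ b` is decided purely by checking that a's label falls in
#' one of b's descendant intervals — no graph traversal at query time.
#'
#' Labels are assigned by depth-first post-order over lexicographically
#' sorted roots and children, so the index is deterministic for a given
#' ontology.
#'
#' @param onto A `semcube_ontology` (its is-a graph must be acyclic, which
#'   the constructor already guarantees).
#' @return An object of class `semcube_interval_index` with fields
#'   `labels` (concept -> integer label), `desc_intervals` and
#'   `anc_intervals` (concept -> two-column matrix of `lo`, `hi`),
#'   `max_label`, and `concept_of_label` (label -> concept id).
#' @export
build_interval_index <- function(onto) {
  stopifnot(inherits(onto, "semcube_ontology"))
  ids <- sort(concept_ids(onto))
  n <- length(ids)
  g <- ontology_graph(ids, onto$isa_edges)

  # children list (edges run child -> parent)
  kids <- lapply(ids, function(v) {
    sort(names(igraph::neighbors(g, v, mode = "in")))
  })
  names(kids) <- ids
  parents_of <- lapply(ids, function(v) {
    names(igraph::neighbors(g, v, mode = "out"))
  })
  names(parents_of) <- ids
  roots <- ids[vapply(parents_of, length, integer(1)) == 0L]

  # iterative post-order DFS over sorted roots/children; first-visit labels
  label <- integer(0)
  next_label <- 1L
  for (r in roots) {
    stack <- list(list(node = r, child_i = 0L))
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      node <- top$node
      ch <- kids[[node]]
      if (top$child_i < length(ch)) {
        stack[[length(stack)]]$child_i <- top$child_i + 1L
        nxt <- ch[top$child_i + 1L]
        if (!(nxt %in% names(label))) {
          stack[[length(stack) + 1L]] <- list(node = nxt, child_i = 0L)
        }
      } else {
        if (!(node %in% names(label))) {
          label[node] <- next_label
          next_label <- next_label + 1L
        }
        stack[[length(stack)]] <- NULL
      }
    }
  }
  stopifnot(length(label) == n)

  # reflexive closure label sets via igraph reachability (build time only)
  desc_intervals <- vector("list", n)
  anc_intervals <- vector("list", n)
  names(desc_intervals) <- names(anc_intervals) <- ids
  for (v in ids) {
    d <- names(igraph::subcomponent(g, v, mode = "in"))   # descendants + self
    a <- names(igraph::subcomponent(g, v, mode = "out"))  # ancestors + self
    desc_intervals[[v]] <- coalesce_labels(unname(label[d]))
    anc_intervals[[v]] <- coalesce_labels(unname(label[a]))
  }
  concept_of_label <- character(n)
  concept_of_label[label[ids]] <- ids
  structure(
    list(labels = label[ids], desc_intervals = desc_intervals,
         anc_intervals = anc_intervals, max_label = n,
         concept_of_label = concept_of_label),
    class = "semcube_interval_index"
  )
}

# sorted integer labels -> coalesced closed intervals as a matrix [lo, hi]
coalesce_labels <- function(labs) {
  labs <- sort(unique(as.integer(labs)))
  if (length(labs) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("lo", "hi"))))
  }
  breaks <- c(0L, which(diff(labs) > 1L), length(labs))
  lo <- labs[breaks[-length(breaks)] + 1L]
  hi <- labs[breaks[-1L]]
  matrix(c(lo, hi), ncol = 2, dimnames = list(NULL, c("lo", "hi")))
}

#' @export
print.semcube_interval_index <- function(x, ...) {
  cat(sprintf("<semcube_interval_index> %d concepts, labels 1..%d\n",
              length(x$labels), x$max_label))
  invisible(x)
}

check_indexed <- function(index, ids) {
  unknown <- setdiff(ids, names(index$labels))
  if (length(unknown) > 0L) {
    stop("concept id(s) not in interval index: ",
         paste(unknown, collapse = ", "))
  }
}

#' Is every interval of one set contained in the other set?
#'
#' The primitive of the interval algebra: `inner` is subsumed by `outer`
#' when each of its closed intervals lies inside some interval of `outer`.
#'
#' @param inner,outer Two-column integer matrices of closed intervals
#'   (`lo`, `hi`).
#' @return Logical scalar.
#' @export
intervals_subsumed <- function(inner, outer) {
  if (nrow(inner) == 0L) return(TRUE)
  if (nrow(outer) == 0L) return(FALSE)
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, "lo"] <= inner[i, "lo"] & inner[i, "hi"] <= outer[, "hi"])
  }, logical(1)))
}

#' Intersect two interval sets
#'
#' @param a,b Two-column integer matrices of closed intervals.
#' @return Coalesced two-column matrix of the intersection (possibly empty).
#' @export
intervals_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, "lo"], b[, "lo"])
    hi <- pmin(a[i, "hi"], b[, "hi"])
    ok <- lo <= hi
    if (any(ok)) out[[length(out) + 1L]] <- cbind(lo = lo[ok], hi = hi[ok])
  }
  if (length(out) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("lo", "hi"))))
  }
  m <- do.call(rbind, out)
  coalesce_labels(unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2])))
}

#' Taxonomic subsumption query (a ≼ b)
#'
#' True iff `a` is a reflexive descendant of `b`, decided by interval
#' containment: a's descendant intervals must all lie within b's descendant
#' space (equivalently, a's own label falls in b's descendant cover).
#'
#' @param index A `semcube_interval_index`.
#' @param a,b Concept ids.
#' @return Logical scalar.
#' @export
is_descendant <- function(index, a, b) {
  check_indexed(index, c(a, b))
  intervals_subsumed(index$desc_intervals[[a]], index$desc_intervals[[b]])
}

#' Common (reflexive) ancestors of two concepts
#'
#' Computed by intersecting the two ancestor interval sets (L+) and mapping
#' the surviving labels back to concept ids.
#'
#' @param index A `semcube_interval_index`.
#' @param a,b Concept ids.
#' @return Character vector of concept ids (sorted).
#' @export
common_ancestors <- function(index, a, b) {
  check_indexed(index, c(a, b))
  inter <- intervals_intersect(index$anc_intervals[[a]],
                               index$anc_intervals[[b]])
  if (nrow(inter) == 0L) return(character(0))
  labs <- unlist(lapply(seq_len(nrow(inter)),
                        function(i) inter[i, "lo"]:inter[i, "hi"]))
  sort(index$concept_of_label[labs])
}

#' Reflexive descendants of a concept
#'
#' Resolved from the descendant interval set, so `descendants(index, c)`
#' equals `{x : is_descendant(index, x, c)}`.
#'
#' @param index A `semcube_interval_index`.
#' @param c_id Concept id.
#' @return Character vector of concept ids (sorted, includes `c_id`).
#' @export
descendants <- function(index, c_id) {
  check_indexed(index, c_id)
  ints <- index$desc_intervals[[c_id]]
  labs <- unlist(lapply(seq_len(nrow(ints)),
                        function(i) ints[i, "lo"]:ints[i, "hi"]))
  sort(index$concept_of_label[labs])
}

#' Full subsumption matrix from an interval index
#'
#' Vectorized evaluation of `is_descendant` for every ordered concept pair:
#' entry (a, b) is TRUE iff a ≼ b, decided by label-in-interval containment.
#' Useful for exhaustive antichain checks and oracle comparisons.
#'
#' @param index A `semcube_interval_index`.
#' @return Logical matrix with concept ids as dimnames; `m[a, b]` is a ≼ b.
#' @export
subsumption_matrix <- function(index) {
  ids <- names(index$labels)
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  labs <- index$labels
  for (b in ids) {
    ints <- index$desc_intervals[[b]]
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(ints))) {
      inside <- inside | (labs >= ints[i, "lo"] & labs <= ints[i, "hi"])
    }
    m[, b] <- inside
  }
  m
}
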