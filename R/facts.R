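#' Maximum taxonomy depth of an ontology
#'
#' Longest is-a chain length in edges, used as the default `gamma`
#' normalizer of the shared-ancestor affinity term.
#'
#' @param onto A `semcube_ontology`.
#' @return Integer >= 0.
#' @export
taxonomy_depth <- function(onto) {
  g <- ontology_graph(concept_ids(onto), onto$isa_edges)
  if (igraph::ecount(g) == 0L) return(0L)
  # edges run child -> parent, so reversing the topological order yields
  # parents before children for the depth DP
  ord <- names(igraph::topo_sort(g, mode = "out"))
  depth <- stats::setNames(integer(length(ord)), ord)
  for (v in rev(ord)) {
    par <- names(igraph::neighbors(g, v, mode = "out"))
    depth[v] <- if (length(par) == 0L) 0L else max(depth[par]) + 1L
  }
  max(depth)
}

#' Build the concept affinity matrix of a document
#'
#' Captures pairwise affinity among the distinct concepts annotated in one
#' document as the entrywise sum of four symmetric components:
#' * `isa`: 1 when one concept properly subsumes the other;
#' * `anc`: number of shared proper ancestors divided by `gamma`;
#' * `rel`: 1 when a named relation links the two concepts (either
#'   direction);
#' * `sents`: 1 when the concepts co-occur in a sentence and are not in
#'   conflict (candidates of the same ambiguous annotation).
#' The diagonal is forced to zero: self-affinity would distort the Laplacian
#' normalization applied downstream.
#'
#' @param annotations Annotation data.frame of one document (see
#'   [annotate_chunk()]).
#' @param onto The reference `semcube_ontology` (for named relations).
#' @param index Interval index over the ontology.
#' @param gamma Positive normalizer for the ancestor term; default the
#'   maximum taxonomy depth (at least 1).
#' @return A `semcube_affinity` with fields `concepts`, `M`, `components`
#'   (the four summands), `gamma`.
#' @export
build_affinity_matrix <- function(annotations, onto, index, gamma = NULL) {
  if (is.null(gamma)) gamma <- max(1L, taxonomy_depth(onto))
  stopifnot(gamma > 0)
  concepts <- sort(unique(unlist(annotations$candidates)))
  check_indexed(index, concepts)
  n <- length(concepts)
  zero <- matrix(0, n, n, dimnames = list(concepts, concepts))
  comp <- list(isa = zero, anc = zero, rel = zero, sents = zero)
  if (n >= 2L) {
    sub <- subsumption_matrix(index)[concepts, concepts, drop = FALSE]
    strict <- sub | t(sub)
    diag(strict) <- FALSE
    comp$isa[strict] <- 1

    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        ca <- common_ancestors(index, concepts[i], concepts[j])
        ca <- setdiff(ca, c(concepts[i], concepts[j]))
        comp$anc[i, j] <- comp$anc[j, i] <- length(ca) / gamma
      }
    }
    rel <- onto$relations
    if (nrow(rel) > 0L) {
      hit <- rel$source_id %in% concepts & rel$target_id %in% concepts
      for (k in which(hit)) {
        comp$rel[rel$source_id[k], rel$target_id[k]] <- 1
        comp$rel[rel$target_id[k], rel$source_id[k]] <- 1
      }
      diag(comp$rel) <- 0
    }
    # sentence co-occurrence, suppressed for conflicting candidates
    conflict <- zero > 1  # all-FALSE logical
    for (k in seq_len(nrow(annotations))) {
      cds <- annotations$candidates[[k]]
      if (length(cds) > 1L) conflict[cds, cds] <- TRUE
    }
    for (s in unique(annotations$sentence)) {
      in_s <- unique(unlist(annotations$candidates[annotations$sentence == s]))
      if (length(in_s) > 1L) comp$sents[in_s, in_s] <- 1
    }
    comp$sents[conflict] <- 0
    diag(comp$sents) <- 0
  }
  M <- comp$isa + comp$anc + comp$rel + comp$sents
  structure(list(concepts = concepts, M = M, components = comp,
                 gamma = gamma),
            class = "semcube_affinity")
}

#' Rank concepts by regularized label propagation
#'
#' Normalizes the affinity matrix with the symmetric Laplacian operator,
#' `S = D^{-1/2} M D^{-1/2}` (rows/columns of isolated concepts set to
#' zero), and returns the closed-form solution
#' `R = (1 - alpha) (I - alpha S)^{-1} Y`
#' of the regularization problem — equivalently the fixed point of the
#' iteration `R <- alpha S R + (1 - alpha) Y`. `alpha` in `[0, 1)` controls
#' smoothing; `alpha = 0` returns `Y` unchanged, and an isolated concept
#' keeps rank `(1 - alpha) Y_i`.
#'
#' @param M A `semcube_affinity` or plain symmetric non-negative matrix.
#' @param Y Numeric vector over the matrix's concepts.
#' @param alpha Smoothing parameter in `[0, 1)`; default 0.9.
#' @return A `semcube_propagation` with fields `Y`, `S`, `alpha`, `R`.
#' @export
propagate <- function(M, Y, alpha = 0.9) {
  if (inherits(M, "semcube_affinity")) M <- M$M
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  stopifnot(length(Y) == nrow(M))
  deg <- rowSums(M)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- M * (dinv %o% dinv)
  A <- diag(nrow(M)) - alpha * S
  R <- tryCatch(
    (1 - alpha) * solve(A, Y),
    error = function(e) {
      stop(sprintf(
        "propagation solve failed (condition number %.3g): %s",
        kappa(A), conditionMessage(e)))
    })
  R <- as.numeric(R)
  names(R) <- rownames(M)
  structure(list(Y = Y, S = S, alpha = alpha, R = R),
            class = "semcube_propagation")
}

#' Iteratively disambiguate a document's ambiguous annotations
#'
#' For each ambiguous annotation A (in document order): set `Y_i = 0` for
#' candidates of A and 1 for every other annotated concept, propagate over
#' the affinity matrix, and reject the members of A scoring strictly below
#' the maximum score attained *within A* (ties all survive). Rejected
#' concepts are deleted from the matrix and from every annotation's
#' candidate set; passes repeat until one rejects nothing, which always
#' happens because each rejecting pass strictly shrinks the concept set.
#'
#' @param annotations Annotation data.frame of one document.
#' @param M A `semcube_affinity` built over the same annotations.
#' @param alpha Smoothing parameter (default 0.9).
#' @return List with `annotations` (reduced candidate sets, ambiguity flags
#'   updated, emptied annotations dropped), `M` (reduced matrix), `concepts`
#'   (survivors), `rejected` (data.frame concept/pass).
#' @export
disambiguate <- function(annotations, M, alpha = 0.9) {
  stopifnot(inherits(M, "semcube_affinity"))
  mat <- M$M
  rejected <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    any_rejection <- FALSE
    for (k in seq_len(nrow(annotations))) {
      cds <- annotations$candidates[[k]]
      cds <- intersect(cds, rownames(mat))
      if (length(cds) < 2L) next
      Y <- as.numeric(!(rownames(mat) %in% cds))
      pr <- propagate(mat, Y, alpha)
      sc <- pr$R[cds]
      keep <- cds[sc >= max(sc)]
      drop <- setdiff(cds, keep)
      if (length(drop) > 0L) {
        any_rejection <- TRUE
        for (d in drop) {
          rejected[[length(rejected) + 1L]] <- data.frame(
            concept = d, pass = pass, stringsAsFactors = FALSE)
        }
        mat <- mat[!(rownames(mat) %in% drop), !(colnames(mat) %in% drop),
                   drop = FALSE]
        annotations$candidates <- lapply(annotations$candidates,
                                         function(x) setdiff(x, drop))
      }
    }
    if (!any_rejection) break
  }
  n_cand <- vapply(annotations$candidates, length, integer(1))
  annotations$ambiguous <- n_cand > 1L
  annotations <- annotations[n_cand > 0L, , drop = FALSE]
  rej <- if (length(rejected) > 0L) do.call(rbind, rejected) else
    data.frame(concept = character(), pass = integer(),
               stringsAsFactors = FALSE)
  M$M <- mat
  M$concepts <- rownames(mat)
  M$components <- lapply(M$components, function(cm) {
    cm[rownames(mat), rownames(mat), drop = FALSE]
  })
  list(annotations = annotations, M = M, concepts = rownames(mat),
       rejected = rej)
}

#' Reduce a disambiguated document to a multidimensional fact
#'
#' `Y` holds each concept's mention frequency in the document; the
#' propagated rank vector `R` then selects, per dimension, the top-scored
#' concept present in the document (ties broken by higher frequency, then
#' lexicographic id). Dimensions without any annotated concept get `NA`.
#'
#' @param annotations Disambiguated annotation data.frame.
#' @param M The (reduced) `semcube_affinity`.
#' @param schema A `semcube_schema`.
#' @param alpha Smoothing parameter (default 0.9).
#' @param doc_id Document id for the fact.
#' @return A `semcube_fact` with fields `doc_id`, `assignment` (named
#'   character, NA for null), `rank_vector`, `concept_frequencies`.
#' @export
build_fact <- function(annotations, M, schema, alpha = 0.9, doc_id = NULL) {
  stopifnot(inherits(schema, "semcube_schema"))
  if (length(schema$dimensions) == 0L) stop("schema has no dimensions")
  if (is.null(doc_id)) {
    doc_id <- if (nrow(annotations) > 0L) annotations$doc_id[1] else "doc"
  }
  concepts <- M$concepts
  freq <- stats::setNames(numeric(length(concepts)), concepts)
  for (cds in annotations$candidates) {
    cds <- intersect(cds, concepts)
    freq[cds] <- freq[cds] + 1
  }
  R <- if (length(concepts) > 0L) {
    propagate(M, as.numeric(freq), alpha)$R
  } else {
    stats::setNames(numeric(0), character(0))
  }
  assignment <- stats::setNames(rep(NA_character_,
                                    length(schema$dimensions)),
                                names(schema$dimensions))
  for (nm in names(schema$dimensions)) {
    present <- intersect(concepts, schema$dimensions[[nm]])
    if (length(present) == 0L) next
    sc <- R[present]
    best <- present[sc == max(sc)]
    if (length(best) > 1L) {
      f <- freq[best]
      best <- best[f == max(f)]
      best <- sort(best)[1]
    }
    assignment[nm] <- best
  }
  structure(list(doc_id = doc_id, assignment = assignment,
                 rank_vector = R, concept_frequencies = freq),
            class = "semcube_fact")
}

#' Run the full per-document normalization (affinity, disambiguation, fact)
#'
#' @param annotations Annotation data.frame of one document.
#' @param onto,index,schema Reference ontology, its interval index and the
#'   multidimensional schema.
#' @param alpha,gamma See [propagate()] and [build_affinity_matrix()].
#' @param doc_id Document id.
#' @return List with `fact` (a `semcube_fact`), `annotations`, `rejected`.
#' @export
normalize_document <- function(annotations, onto, index, schema,
                               alpha = 0.9, gamma = NULL, doc_id = NULL) {
  M <- build_affinity_matrix(annotations, onto, index, gamma)
  dis <- disambiguate(annotations, M, alpha)
  fact <- build_fact(dis$annotations, dis$M, schema, alpha, doc_id)
  list(fact = fact, annotations = dis$annotations, rejected = dis$rejected)
}

#' Collect per-document facts into a store
#'
#' @param facts List of `semcube_fact`.
#' @param schema The `semcube_schema` the facts were built against.
#' @return A `semcube_fact_store` with fields `facts` (named by doc id),
#'   `schema`, `n_col`.
#' @export
fact_store <- function(facts, schema) {
  names(facts) <- vapply(facts, function(f) f$doc_id, character(1))
  if (anyDuplicated(names(facts))) stop("duplicate doc ids in fact list")
  structure(list(facts = facts, schema = schema, n_col = length(facts)),
            class = "semcube_fact_store")
}

#' @export
print.semcube_fact_store <- function(x, ...) {
  cat(sprintf("<semcube_fact_store> %d facts over %d dimension(s)\n",
              x$n_col, length(x$schema$dimensions)))
  invisible(x)
}

#' Collection-level relevance of a concept
#'
#' Aggregates a per-concept score over the concept's reflexive descendants
#' within its dimension. `score_mode = "hits"` scores a concept by the
#' number of facts assigned exactly to it; `"rank"` sums the propagated
#' rank `R^d[c']` over the documents whose fact assigns `c'`.
#'
#' @param store A `semcube_fact_store`.
#' @param c_id Concept id (must belong to `dimension`).
#' @param dimension Dimension name.
#' @param aggregator `"sum"` (default) or `"avg"`.
#' @param score_mode `"hits"` (default) or `"rank"`.
#' @param index Interval index covering the dimension's concepts.
#' @return Numeric scalar.
#' @export
concept_relevance <- function(store, c_id, dimension,
                              aggregator = c("sum", "avg"),
                              score_mode = c("hits", "rank"), index) {
  aggregator <- match.arg(aggregator)
  score_mode <- match.arg(score_mode)
  dims <- store$schema$dimensions
  if (!dimension %in% names(dims) || !(c_id %in% dims[[dimension]])) {
    stop("concept ", c_id, " is not in dimension ", dimension)
  }
  desc <- intersect(descendants(index, c_id), dims[[dimension]])
  assigned <- vapply(store$facts, function(f) f$assignment[[dimension]],
                     character(1))
  score_one <- function(cp) {
    hit_docs <- which(!is.na(assigned) & assigned == cp)
    if (score_mode == "hits") {
      length(hit_docs)
    } else {
      sum(vapply(store$facts[hit_docs],
                 function(f) unname(f$rank_vector[cp]), numeric(1)))
    }
  }
  scores <- vapply(desc, score_one, numeric(1))
  if (aggregator == "sum") sum(scores) else mean(scores)
}

#' Evaluate system concepts against a gold standard
#'
#' A system concept of a document counts as correct when it is
#' alignment-related to some gold concept of that document, where alignment
#' means either concept subsumes the other in the merged taxonomy.
#' Precision, recall and F-score are micro-averaged over the collection.
#'
#' @param system A `semcube_fact_store` (non-null assignments are the system
#'   output per document) or a named list doc_id -> character vector.
#' @param gold Named list doc_id -> character vector of gold concept ids.
#' @param index Interval index over the merged taxonomy.
#' @return List with `precision`, `recall`, `f_score`.
#' @export
evaluate_against_gold <- function(system, gold, index) {
  if (length(gold) == 0L || all(vapply(gold, length, integer(1)) == 0L)) {
    stop("empty gold standard")
  }
  if (inherits(system, "semcube_fact_store")) {
    system <- lapply(system$facts, function(f) {
      unname(f$assignment[!is.na(f$assignment)])
    })
  }
  aligned <- function(a, b) {
    is_descendant(index, a, b) || is_descendant(index, b, a)
  }
  tp_p <- 0L; n_sys <- 0L; tp_r <- 0L; n_gold <- 0L
  for (d in union(names(system), names(gold))) {
    s <- unique(system[[d]]); g <- unique(gold[[d]])
    n_sys <- n_sys + length(s); n_gold <- n_gold + length(g)
    for (x in s) {
      if (any(vapply(g, function(y) aligned(x, y), logical(1)))) {
        tp_p <- tp_p + 1L
      }
    }
    for (y in g) {
      if (any(vapply(s, function(x) aligned(x, y), logical(1)))) {
        tp_r <- tp_r + 1L
      }
    }
  }
  p <- if (n_sys > 0L) tp_p / n_sys else 0
  r <- if (n_gold > 0L) tp_r / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_score = f)
}
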