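#' Construct a reference ontology
#'
#' An ontology holds the concept inventory of a knowledge resource: concepts
#' with semantic types, the is-a taxonomy (a DAG over concept ids), optional
#' named relations, and the lexicon of surface strings by which concepts are
#' mentioned in text.
#'
#' @param concepts data.frame with columns `id`, `label`, `semantic_types`
#'   (pipe-separated string of type codes, possibly empty), `source`.
#' @param isa_edges data.frame with columns `child_id`, `parent_id`. Must be
#'   acyclic; every endpoint must be a declared concept.
#' @param relations data.frame with columns `relation_name`, `source_id`,
#'   `target_id` (may be empty).
#' @param lexicon data.frame with columns `concept_id`, `surface_string`.
#'   Strings must be non-empty; a string may map to several concepts
#'   (ambiguity).
#' @return An object of class `semcube_ontology`.
#' @export
ontology <- function(concepts,
                     isa_edges = empty_isa(),
                     relations = empty_relations(),
                     lexicon = empty_lexicon()) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  isa_edges <- as.data.frame(isa_edges, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  lexicon <- as.data.frame(lexicon, stringsAsFactors = FALSE)

  required <- c("id", "label", "semantic_types", "source")
  missing_cols <- setdiff(required, names(concepts))
  if (length(missing_cols) > 0L) {
    stop("concepts table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(concepts$id)) {
    dup <- unique(concepts$id[duplicated(concepts$id)])
    stop("duplicate concept id(s): ", paste(dup, collapse = ", "))
  }
  ids <- concepts$id
  if (nrow(isa_edges) > 0L) {
    unknown <- setdiff(unique(c(isa_edges$child_id, isa_edges$parent_id)), ids)
    if (length(unknown) > 0L) {
      stop("is-a edge endpoint(s) not declared as concepts: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (nrow(lexicon) > 0L) {
    if (any(!nzchar(lexicon$surface_string))) {
      stop("lexicon contains empty surface strings")
    }
    unknown <- setdiff(unique(lexicon$concept_id), ids)
    if (length(unknown) > 0L) {
      stop("lexicon refers to unknown concept(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  g <- ontology_graph(ids, isa_edges)
  if (!igraph::is_dag(g)) {
    cyc <- isa_edges[find_cycle_edges(g, isa_edges), , drop = FALSE]
    stop("is-a graph contains a directed cycle; offending edge(s): ",
         paste(sprintf("%s->%s", cyc$child_id, cyc$parent_id), collapse = ", "))
  }
  structure(
    list(concepts = concepts, isa_edges = isa_edges,
         relations = relations, lexicon = lexicon),
    class = "semcube_ontology"
  )
}

empty_isa <- function() {
  data.frame(child_id = character(), parent_id = character(),
             stringsAsFactors = FALSE)
}
empty_relations <- function() {
  data.frame(relation_name = character(), source_id = character(),
             target_id = character(), stringsAsFactors = FALSE)
}
empty_lexicon <- function() {
  data.frame(concept_id = character(), surface_string = character(),
             stringsAsFactors = FALSE)
}

# igraph over concept ids, edges child -> parent (direction of ≼).
ontology_graph <- function(ids, isa_edges) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(isa_edges) > 0L) {
    g <- igraph::add_edges(g, rbind(isa_edges$child_id, isa_edges$parent_id))
  }
  g
}

# Identify edges participating in a cycle (feedback edges of any strongly
# connected component with >1 vertex or a self-loop).
find_cycle_edges <- function(g, isa_edges) {
  comp <- igraph::components(g, mode = "strong")
  bad_v <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
  isa_edges$child_id %in% bad_v & isa_edges$parent_id %in% bad_v |
    isa_edges$child_id == isa_edges$parent_id
}

#' @export
print.semcube_ontology <- function(x, ...) {
  cat(sprintf(
    "<semcube_ontology> %d concepts, %d is-a edges, %d relations, %d lexicon rows\n",
    nrow(x$concepts), nrow(x$isa_edges), nrow(x$relations), nrow(x$lexicon)))
  invisible(x)
}

#' Concept ids of an ontology
#' @param onto A `semcube_ontology`.
#' @return Character vector of concept ids.
#' @export
concept_ids <- function(onto) onto$concepts$id

#' Semantic types of each concept as a named list
#' @param onto A `semcube_ontology`.
#' @return Named list, concept id -> character vector of type codes.
#' @export
semantic_types <- function(onto) {
  out <- strsplit(onto$concepts$semantic_types, "|", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- onto$concepts$id
  out
}

#' Extract the fragment of an ontology induced by a concept signature
#'
#' Returns the sub-ontology spanned by the signature concepts. With
#' `include_ancestors = TRUE` (the default) every ancestor of a signature
#' concept is retained as well, so taxonomic context needed for dimension
#' building is preserved. With `include_ancestors = FALSE` only the signature
#' itself is kept and a contraction edge (x, z) is added whenever every
#' intermediate concept on every x -> z path was dropped, so reachability
#' among retained concepts is unchanged either way.
#'
#' @param onto A `semcube_ontology`.
#' @param signature Character vector of concept ids observed in a collection.
#' @param include_ancestors Keep all ancestors of the signature (default TRUE).
#' @return A `semcube_ontology` restricted to the retained concepts.
#' @export
extract_fragment <- function(onto, signature, include_ancestors = TRUE) {
  stopifnot(inherits(onto, "semcube_ontology"))
  unknown <- setdiff(signature, concept_ids(onto))
  if (length(unknown) > 0L) {
    stop("signature contains unknown concept id(s): ",
         paste(unknown, collapse = ", "))
  }
  g <- ontology_graph(concept_ids(onto), onto$isa_edges)
  keep <- unique(signature)
  if (include_ancestors) {
    anc <- unlist(lapply(signature, function(s) {
      names(igraph::subcomponent(g, s, mode = "out"))
    }))
    keep <- unique(c(keep, anc))
  }
  keep <- sort(keep)
  sub_edges <- onto$isa_edges[onto$isa_edges$child_id %in% keep &
                                onto$isa_edges$parent_id %in% keep, ,
                              drop = FALSE]
  # Contraction: connect each retained concept x to its closest retained
  # strict ancestors (those z with no retained m strictly between x and z in
  # the full ontology). Together with the surviving original edges this
  # preserves reachability among retained concepts exactly.
  reach <- matrix(FALSE, length(keep), length(keep),
                  dimnames = list(keep, keep))
  for (x in keep) {
    anc_x <- intersect(names(igraph::subcomponent(g, x, mode = "out")), keep)
    reach[x, anc_x] <- TRUE
  }
  diag(reach) <- FALSE  # strict ancestors only
  extra <- list()
  for (x in keep) {
    anc_x <- keep[reach[x, ]]
    for (z in anc_x) {
      between <- setdiff(anc_x[reach[anc_x, z, drop = TRUE]], z)
      if (length(between) == 0L) {
        extra[[length(extra) + 1L]] <- c(x, z)
      }
    }
  }
  if (length(extra) > 0L) {
    extra <- do.call(rbind, extra)
    sub_edges <- rbind(sub_edges,
                       data.frame(child_id = extra[, 1], parent_id = extra[, 2],
                                  stringsAsFactors = FALSE))
  }
  sub_edges <- unique(sub_edges)
  sub_edges <- sub_edges[order(sub_edges$child_id, sub_edges$parent_id), ,
                         drop = FALSE]
  rownames(sub_edges) <- NULL
  ontology(
    concepts = onto$concepts[onto$concepts$id %in% keep, , drop = FALSE],
    isa_edges = sub_edges,
    relations = onto$relations[onto$relations$source_id %in% keep &
                                 onto$relations$target_id %in% keep, ,
                               drop = FALSE],
    lexicon = onto$lexicon[onto$lexicon$concept_id %in% keep, , drop = FALSE]
  )
}
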