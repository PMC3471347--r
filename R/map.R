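#' Initialize a conceptual-map state
#'
#' A conceptual map is a sequence of layers, one per (dimension, level)
#' pair, each showing a set of visible concepts; bridges connect concepts of
#' adjacent layers. The engine is UI-free: every operation returns data.
#'
#' @param schema A `semcube_schema` with levels.
#' @param layers data.frame with columns `dimension`, `depth` selecting one
#'   level per layer, in display order.
#' @return A `semcube_map_state` with fields `layers`, `visible` (named by
#'   `dimension:depth`), `bridges`, `query_highlight`, `expanded`.
#' @export
map_state <- function(schema, layers) {
  visible <- list()
  for (i in seq_len(nrow(layers))) {
    nm <- layers$dimension[i]
    lv <- schema$levels[[nm]]
    hit <- Filter(function(l) l$depth == layers$depth[i], lv)
    if (length(hit) == 0L) {
      stop("dimension ", nm, " has no level at depth ", layers$depth[i])
    }
    visible[[layer_key(nm, layers$depth[i])]] <- hit[[1]]$members
  }
  structure(list(schema = schema, layers = layers, visible = visible,
                 bridges = empty_bridges(), query_highlight = character(0),
                 expanded = character(0)),
            class = "semcube_map_state")
}

layer_key <- function(dimension, depth) paste(dimension, depth, sep = ":")

state_layer_of <- function(state, dimension) {
  i <- which(state$layers$dimension == dimension)
  if (length(i) == 0L) stop("no layer for dimension ", dimension)
  layer_key(dimension, state$layers$depth[i[1]])
}

#' Direct children of a concept within its dimension
#'
#' "Children" are the direct successors of `c_id` in the transitive
#' reduction of the dimension-restricted subsumption order, so a concept
#' reachable through two paths appears once and only under its direct
#' parent.
#'
#' @param schema A `semcube_schema`.
#' @param dimension Dimension name.
#' @param c_id Concept id.
#' @param index Interval index.
#' @return Character vector of concept ids (possibly empty).
#' @export
dimension_children <- function(schema, dimension, c_id, index) {
  members <- schema$dimensions[[dimension]]
  if (is.null(members)) stop("unknown dimension ", dimension)
  sub <- subsumption_matrix(index)[members, members, drop = FALSE]
  strict <- sub; diag(strict) <- FALSE
  below <- members[strict[, c_id]]  # strict descendants of c within dim
  direct <- below[vapply(below, function(x) {
    # x is a direct child iff no m strictly between x and c
    mids <- members[strict[x, ] & strict[, c_id]]
    length(mids) == 0L
  }, logical(1))]
  sort(direct)
}

#' Drill down on a visible concept
#'
#' Replaces `c_id` in its layer's visible set by its direct children within
#' the dimension (marked expanded) and recomputes the bridges touching the
#' affected layer from the fact store.
#'
#' @param state A `semcube_map_state`.
#' @param dimension Dimension name.
#' @param c_id Visible concept to expand.
#' @param index Interval index.
#' @param store Optional `semcube_fact_store`; when given, bridges touching
#'   the layer are recomputed with `measure`/`delta`/`min_support`.
#' @param measure,delta,min_support Bridge scoring configuration.
#' @return List with `state` (updated) and `children` (the exposed ids;
#'   empty when `c_id` is a leaf, which leaves the state unchanged).
#' @export
drill_down <- function(state, dimension, c_id, index, store = NULL,
                       measure = "interest_factor", delta = 1,
                       min_support = 2L) {
  key <- state_layer_of(state, dimension)
  if (!(c_id %in% state$visible[[key]])) {
    stop("concept ", c_id, " is not visible in dimension ", dimension)
  }
  kids <- dimension_children(state$schema, dimension, c_id, index)
  if (length(kids) == 0L) {
    return(list(state = state, children = character(0)))
  }
  state$visible[[key]] <- sort(c(setdiff(state$visible[[key]], c_id), kids))
  state$expanded <- sort(unique(c(state$expanded, kids)))
  state$bridges <- state$bridges[state$bridges$c_i != c_id &
                                   state$bridges$c_j != c_id, , drop = FALSE]
  if (!is.null(store)) {
    state <- recompute_bridges(state, index, store, measure, delta,
                               min_support)
  }
  list(state = state, children = kids)
}

# score bridges between every pair of adjacent layers over the current
# visible sets (an ad-hoc antichain-free "level" built from visibility)
recompute_bridges <- function(state, index, store, measure, delta,
                              min_support) {
  n <- nrow(state$layers)
  all_bridges <- empty_bridges()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      li <- list(dimension = state$layers$dimension[i],
                 depth = state$layers$depth[i],
                 members = state$visible[[layer_key(
                   state$layers$dimension[i], state$layers$depth[i])]],
                 virtual = FALSE)
      lj <- list(dimension = state$layers$dimension[i + 1L],
                 depth = state$layers$depth[i + 1L],
                 members = state$visible[[layer_key(
                   state$layers$dimension[i + 1L],
                   state$layers$depth[i + 1L])]],
                 virtual = FALSE)
      li$members <- setdiff(li$members, virtual_root_id(li$dimension))
      lj$members <- setdiff(lj$members, virtual_root_id(lj$dimension))
      if (length(li$members) == 0L || length(lj$members) == 0L) next
      cube <- build_cube(store, li, lj, index)
      all_bridges <- rbind(all_bridges,
                           find_bridges(cube, measure, delta, min_support))
    }
  }
  state$bridges <- all_bridges
  state
}

#' Does a concept contain a sub-concept matching a keyword query?
#'
#' True iff some reflexive descendant of `c_id` inside the dimension has a
#' lexical variant containing every query token (case-insensitive
#' whole-token match).
#'
#' @param schema A `semcube_schema`.
#' @param dimension Dimension name (must contain `c_id`).
#' @param c_id Concept id.
#' @param keywords Non-empty query string.
#' @param onto The `semcube_ontology` (for the lexicon).
#' @param index Interval index.
#' @return Logical scalar.
#' @export
contains_keywords <- function(schema, dimension, c_id, keywords, onto,
                              index) {
  if (!nzchar(trimws(keywords))) stop("empty keyword query")
  if (!(c_id %in% schema$dimensions[[dimension]])) {
    stop("concept ", c_id, " is not in dimension ", dimension)
  }
  q <- tokenize(keywords)$tokens
  if (length(q) == 0L) stop("keyword query has no tokens")
  desc <- intersect(descendants(index, c_id), schema$dimensions[[dimension]])
  lex <- onto$lexicon[onto$lexicon$concept_id %in% desc, , drop = FALSE]
  if (nrow(lex) == 0L) return(FALSE)
  any(vapply(lex$surface_string, function(s) {
    all(q %in% tokenize(s)$tokens)
  }, logical(1)))
}

#' Drill through a concept to its supporting documents
#'
#' Returns the documents whose fact assignment (in the concept's dimension)
#' falls at or below `c_id`, scored by the rank `R^d` of the assigned
#' concept, in descending order (ties by doc id).
#'
#' @param store A `semcube_fact_store`.
#' @param c_id Concept id.
#' @param index Interval index.
#' @param dimension Dimension to search; default the concept's own.
#' @return data.frame with `doc_id`, `score`, `concept` (the assigned
#'   descendant that matched).
#' @export
drill_through_concept <- function(store, c_id, index, dimension = NULL) {
  if (is.null(dimension)) dimension <- dimension_of(store$schema, c_id)
  if (is.na(dimension)) stop("concept ", c_id, " belongs to no dimension")
  rows <- list()
  for (f in store$facts) {
    a <- f$assignment[[dimension]]
    if (is.na(a)) next
    if (is_descendant(index, a, c_id)) {
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = f$doc_id, score = unname(f$rank_vector[a]), concept = a,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(doc_id = character(), score = numeric(),
                      concept = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$doc_id), , drop = FALSE]
}

#' Drill through a bridge to its supporting documents
#'
#' Documents counted in the bridge's joint support (fact at or below both
#' endpoints), scored by the product of the two endpoint relevances
#' `rel(d, b) = rel(d, c_1) * rel(d, c_2)`, descending (ties by doc id).
#'
#' @param store A `semcube_fact_store`.
#' @param bridge One-row data.frame with `c_i`, `c_j` (as from
#'   [find_bridges()]).
#' @param index Interval index.
#' @param dim_i,dim_j Dimensions of the endpoints; default their own.
#' @return data.frame with `doc_id`, `score`.
#' @export
drill_through_bridge <- function(store, bridge, index, dim_i = NULL,
                                 dim_j = NULL) {
  if (is.null(dim_i)) dim_i <- dimension_of(store$schema, bridge$c_i)
  if (is.null(dim_j)) dim_j <- dimension_of(store$schema, bridge$c_j)
  rows <- list()
  for (f in store$facts) {
    ai <- f$assignment[[dim_i]]; aj <- f$assignment[[dim_j]]
    if (is.na(ai) || is.na(aj)) next
    if (is_descendant(index, ai, bridge$c_i) &&
        is_descendant(index, aj, bridge$c_j)) {
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = f$doc_id,
        score = unname(f$rank_vector[ai]) * unname(f$rank_vector[aj]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(doc_id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$doc_id), , drop = FALSE]
}

#' Prune a map layer by concept removal or selection
#'
#' `mode = "removal"` deletes `c_id` and every bridge touching it;
#' `mode = "selection"` instead deletes every *other* concept of the
#' dimension's layer and their bridges. Pure state operations — nothing is
#' recomputed.
#'
#' @param state A `semcube_map_state`.
#' @param dimension Dimension name.
#' @param c_id Visible concept.
#' @param mode `"removal"` or `"selection"`.
#' @return The updated `semcube_map_state`.
#' @export
prune_state <- function(state, dimension, c_id,
                        mode = c("removal", "selection")) {
  mode <- match.arg(mode)
  key <- state_layer_of(state, dimension)
  if (!(c_id %in% state$visible[[key]])) {
    stop("concept ", c_id, " is not visible in dimension ", dimension)
  }
  gone <- if (mode == "removal") c_id else
    setdiff(state$visible[[key]], c_id)
  state$visible[[key]] <- setdiff(state$visible[[key]], gone)
  state$bridges <- state$bridges[!(state$bridges$c_i %in% gone |
                                     state$bridges$c_j %in% gone), ,
                                 drop = FALSE]
  state
}

#' Export a map state as JSON
#'
#' @param state A `semcube_map_state`.
#' @return JSON string with `layers`, `visible`, `bridges`, `highlights`,
#'   `expanded`.
#' @export
map_state_json <- function(state) {
  jsonlite::toJSON(list(
    layers = state$layers,
    visible = state$visible,
    bridges = state$bridges,
    highlights = state$query_highlight,
    expanded = state$expanded
  ), auto_unbox = TRUE, pretty = TRUE)
}
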