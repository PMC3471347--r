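#' Declare a dimension of the multidimensional schema
#'
#' A dimension is a named semantic group (e.g. Disease, Anatomy) serving as
#' an analysis axis. A concept is admitted into the dimension when it carries
#' one of the selector semantic types or descends from one of the selector
#' root concepts. Priorities resolve concepts matched by several dimensions.
#'
#' @param name Dimension label.
#' @param priority Integer rank; lower wins when a concept matches several
#'   specs. Must be unique across the spec list.
#' @param semantic_types Character vector of admitting type codes.
#' @param roots Character vector of admitting root concept ids.
#' @return A `semcube_dimension_spec`.
#' @export
dimension_spec <- function(name, priority, semantic_types = character(0),
                           roots = character(0)) {
  if (length(semantic_types) + length(roots) == 0L) {
    stop("dimension spec '", name, "' has an empty selector")
  }
  structure(list(name = name, priority = as.integer(priority),
                 semantic_types = semantic_types, roots = roots),
            class = "semcube_dimension_spec")
}

#' Partition an ontology fragment into disjoint dimensions
#'
#' Every concept is assigned to at most one dimension: the highest-priority
#' (lowest number) spec whose selector it matches. Multi-matches are recorded
#' in the conflict report; concepts matching no selector stay unassigned and
#' are excluded from fact building.
#'
#' @param fragment A `semcube_ontology`.
#' @param specs List of `semcube_dimension_spec`.
#' @param index Interval index over `fragment`; built on the fly if NULL.
#' @return A `semcube_schema` with fields `dimensions` (name -> concept ids),
#'   `conflict_report` (data.frame concept/competing/winner), `specs`; levels
#'   are added by [stratify_levels()] or [build_schema()].
#' @export
partition_dimensions <- function(fragment, specs, index = NULL) {
  stopifnot(inherits(fragment, "semcube_ontology"))
  if (length(specs) == 0L) stop("empty dimension spec list")
  prios <- vapply(specs, function(s) s$priority, integer(1))
  if (anyDuplicated(prios)) stop("dimension priorities must be unique")
  specs <- specs[order(prios)]
  if (is.null(index)) index <- build_interval_index(fragment)

  stypes <- semantic_types(fragment)
  ids <- concept_ids(fragment)
  match_spec <- function(spec) {
    by_type <- vapply(ids, function(cid) {
      any(stypes[[cid]] %in% spec$semantic_types)
    }, logical(1))
    by_root <- rep(FALSE, length(ids))
    for (r in intersect(spec$roots, ids)) {
      by_root <- by_root | ids %in% descendants(index, r)
    }
    ids[by_type | by_root]
  }
  matched <- lapply(specs, match_spec)
  names(matched) <- vapply(specs, function(s) s$name, character(1))

  assigned <- character(0)
  dims <- list()
  conflicts <- list()
  for (k in seq_along(specs)) {
    nm <- specs[[k]]$name
    take <- setdiff(matched[[k]], assigned)
    # conflicts: concepts this spec matched that a higher-priority spec took,
    # and concepts taken here that a lower-priority spec also matches
    dims[[nm]] <- sort(take)
    assigned <- c(assigned, take)
  }
  for (cid in unique(unlist(matched))) {
    who <- names(matched)[vapply(matched, function(m) cid %in% m, logical(1))]
    if (length(who) > 1L) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        concept = cid, competing = paste(who, collapse = "|"),
        winner = who[1L], stringsAsFactors = FALSE)
    }
  }
  conflict_report <- if (length(conflicts) > 0L) {
    do.call(rbind, conflicts)
  } else {
    data.frame(concept = character(), competing = character(),
               winner = character(), stringsAsFactors = FALSE)
  }
  structure(list(dimensions = dims, levels = list(),
                 conflict_report = conflict_report, specs = specs),
            class = "semcube_schema")
}

#' @export
print.semcube_schema <- function(x, ...) {
  cat(sprintf("<semcube_schema> %d dimension(s): %s\n", length(x$dimensions),
              paste(sprintf("%s[%d]", names(x$dimensions),
                            vapply(x$dimensions, length, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

virtual_root_id <- function(dimension) paste0("__root__:", dimension)

#' Stratify a dimension into ordered antichain levels
#'
#' Default mode assigns each concept the length of the longest subsumption
#' chain from a maximal concept of the dimension (depth 0 = the maximal
#' concepts). Strata of equal depth can never contain two comparable
#' concepts, so each level is an antichain; and each level's members share a
#' common super-concept inside the dimension. When the dimension has more
#' than one maximal concept a virtual root level is prepended (member id
#' `__root__:<dimension>`, flagged `virtual`) so the common-ancestor
#' constraint stays satisfiable.
#'
#' Mode `"semantic_type"` instead maps the spec's ordered semantic types
#' directly to levels (a concept joins the level of its first matching
#' type); such levels satisfy the antichain constraint only if the types
#' stratify the taxonomy — [validate_schema()] reports violations.
#'
#' @param schema A `semcube_schema` from [partition_dimensions()].
#' @param dimension Dimension name.
#' @param index Interval index over the fragment.
#' @param mode `"depth"` (default) or `"semantic_type"`.
#' @param fragment Required for `"semantic_type"` mode (to read the types).
#' @return Ordered list of levels; each is a list with `dimension`, `depth`,
#'   `members`, `virtual`.
#' @export
stratify_levels <- function(schema, dimension, index, mode = c("depth", "semantic_type"),
                            fragment = NULL) {
  mode <- match.arg(mode)
  if (!dimension %in% names(schema$dimensions)) {
    stop("unknown dimension: ", dimension)
  }
  members <- schema$dimensions[[dimension]]
  if (length(members) == 0L) stop("dimension '", dimension, "' is empty")

  if (mode == "semantic_type") {
    spec <- schema$specs[[which(vapply(schema$specs, function(s) s$name,
                                       character(1)) == dimension)]]
    stypes <- semantic_types(fragment)
    lv <- lapply(seq_along(spec$semantic_types), function(j) {
      mem <- members[vapply(members, function(cid) {
        first <- spec$semantic_types[spec$semantic_types %in% stypes[[cid]]][1]
        identical(first, spec$semantic_types[j])
      }, logical(1))]
      list(dimension = dimension, depth = j - 1L, members = sort(mem),
           virtual = FALSE)
    })
    return(lv[vapply(lv, function(l) length(l$members) > 0L, logical(1))])
  }

  sub <- subsumption_matrix(index)[members, members, drop = FALSE]
  strict <- sub; diag(strict) <- FALSE
  # depth = longest chain (in comparability edges) from a maximal concept
  depth <- integer(length(members)); names(depth) <- members
  # strict[a, b] TRUE means a ≺ b, i.e. the ancestors of x are strict[x, ].
  # An ancestor always has strictly fewer ancestors than its descendant, so
  # sorting by ancestor count gives a valid topological processing order.
  order_by_anc <- members[order(rowSums(strict))]
  for (x in order_by_anc) {
    anc_in_dim <- members[strict[x, ]]
    depth[x] <- if (length(anc_in_dim) == 0L) 0L else max(depth[anc_in_dim]) + 1L
  }
  maximals <- members[rowSums(strict) == 0L]
  levels_list <- lapply(sort(unique(depth)), function(k) {
    list(dimension = dimension, depth = as.integer(k),
         members = sort(names(depth)[depth == k]), virtual = FALSE)
  })
  if (length(maximals) > 1L) {
    root_level <- list(dimension = dimension, depth = 0L,
                       members = virtual_root_id(dimension), virtual = TRUE)
    levels_list <- lapply(levels_list, function(l) {
      l$depth <- l$depth + 1L
      l
    })
    levels_list <- c(list(root_level), levels_list)
  }
  levels_list
}

#' Build and stratify the full schema in one call
#'
#' @inheritParams partition_dimensions
#' @inheritParams stratify_levels
#' @return A `semcube_schema` with `levels` populated for every non-empty
#'   dimension.
#' @export
build_schema <- function(fragment, specs, index = NULL,
                         mode = c("depth", "semantic_type")) {
  mode <- match.arg(mode)
  if (is.null(index)) index <- build_interval_index(fragment)
  schema <- partition_dimensions(fragment, specs, index)
  for (nm in names(schema$dimensions)) {
    if (length(schema$dimensions[[nm]]) > 0L) {
      schema$levels[[nm]] <- stratify_levels(schema, nm, index, mode = mode,
                                             fragment = fragment)
    }
  }
  schema
}

#' Validate a multidimensional schema
#'
#' Report-only check of the schema invariants: pairwise dimension
#' disjointness, per-level antichain (no two comparable members), per-level
#' common ancestor inside the dimension, and coverage (each dimension's
#' non-virtual level members equal its concept set, each concept in exactly
#' one level).
#'
#' @param schema A `semcube_schema` with levels.
#' @param index Interval index over the fragment.
#' @return data.frame with columns `kind`, `dimension`, `detail`; zero rows
#'   iff the schema is valid.
#' @export
validate_schema <- function(schema, index) {
  issues <- list()
  push <- function(kind, dimension, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      kind = kind, dimension = dimension, detail = detail,
      stringsAsFactors = FALSE)
  }
  dims <- schema$dimensions
  nms <- names(dims)
  if (length(nms) > 1L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in seq((i + 1L), length(nms))) {
        ov <- intersect(dims[[i]], dims[[j]])
        if (length(ov) > 0L) {
          push("disjointness", paste(nms[i], nms[j], sep = "/"),
               paste(ov, collapse = ","))
        }
      }
    }
  }
  sub <- subsumption_matrix(index)
  for (nm in names(schema$levels)) {
    lvls <- schema$levels[[nm]]
    real_members <- unlist(lapply(lvls, function(l) {
      if (isTRUE(l$virtual)) character(0) else l$members
    }))
    if (anyDuplicated(real_members)) {
      push("coverage", nm, paste("duplicated across levels:",
           paste(unique(real_members[duplicated(real_members)]), collapse = ",")))
    }
    missing <- setdiff(dims[[nm]], real_members)
    extra <- setdiff(real_members, dims[[nm]])
    if (length(missing) > 0L) {
      push("coverage", nm, paste("missing from levels:",
                                 paste(missing, collapse = ",")))
    }
    if (length(extra) > 0L) {
      push("coverage", nm, paste("not in dimension:",
                                 paste(extra, collapse = ",")))
    }
    for (l in lvls) {
      if (isTRUE(l$virtual) || length(l$members) < 2L) next
      mem <- intersect(l$members, rownames(sub))
      s <- sub[mem, mem, drop = FALSE]
      diag(s) <- FALSE
      if (any(s)) {
        w <- which(s, arr.ind = TRUE)
        pairs <- apply(w, 1L, function(r) {
          paste(mem[r[1]], mem[r[2]], sep = "≼")
        })
        push("antichain", nm,
             sprintf("level %d: %s", l$depth, paste(pairs, collapse = ",")))
      }
      # common ancestor within the dimension (or the virtual root)
      has_virtual <- any(vapply(lvls, function(x) isTRUE(x$virtual), logical(1)))
      if (!has_virtual) {
        anc_common <- Reduce(intersect, lapply(mem, function(cid) {
          rownames(sub)[sub[cid, ]]
        }))
        if (length(intersect(anc_common, dims[[nm]])) == 0L) {
          push("common_ancestor", nm,
               sprintf("level %d has no common ancestor in dimension", l$depth))
        }
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(kind = character(), dimension = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Dimension of a concept under a schema
#' @param schema A `semcube_schema`.
#' @param c_id Concept id.
#' @return Dimension name, or NA if the concept is unassigned.
#' @export
dimension_of <- function(schema, c_id) {
  for (nm in names(schema$dimensions)) {
    if (c_id %in% schema$dimensions[[nm]]) return(nm)
  }
  NA_character_
}
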