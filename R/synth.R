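#' Configuration for the synthetic fixture generator
#'
#' Defines the study conditions every synthetic run emulates: a seeded
#' random DAG taxonomy split into disjoint per-dimension subtrees, a lexicon
#' with a controlled share of ambiguous strings, a Zipfian background
#' vocabulary, and a corpus with planted concept mentions and planted
#' concept-pair associations at a configured lift.
#'
#' @param n_concepts Total concepts across dimensions (default 60).
#' @param max_depth Maximum taxonomy depth in edges (default 4).
#' @param branching Integer range `c(min, max)` of children per node
#'   (default `c(2, 4)`).
#' @param n_dimensions Number of disjoint dimensions (default 3).
#' @param ambiguity_rate Fraction of lexicon strings shared by two concepts
#'   in different dimensions, in `[0, 1]` (default 0.2).
#' @param n_docs Documents to generate (default 100).
#' @param mentions_per_doc Range `c(lo, hi)`: how many dimensions (beyond
#'   those driven by planted pairs) each document mentions (default
#'   `c(1, 3)`).
#' @param planted_pairs data.frame with columns `a`, `b`, `lift` (may be
#'   empty): concept pairs to co-occur at `lift` times the independence
#'   baseline. Leave `a`/`b` as `NA` to let the generator pick leaf concepts
#'   from the first two dimensions.
#' @param pair_prob Marginal mention probability of each planted-pair
#'   concept (default 0.1).
#' @param zipf_exponent Zipf exponent of the background/filler vocabulary
#'   (default 1.1).
#' @param n_filler_words Filler vocabulary size (default 400), disjoint
#'   from the lexicon vocabulary so annotation noise comes only from
#'   planted ambiguity.
#' @param dag_extra_parent_prob Probability a non-root concept gets a second
#'   parent inside its dimension, making the taxonomy a proper DAG
#'   (default 0.15).
#' @param seed Integer seed driving all randomness (default 1).
#' @return A `semcube_synth_config`.
#' @export
synth_config <- function(n_concepts = 60L, max_depth = 4L,
                         branching = c(2L, 4L), n_dimensions = 3L,
                         ambiguity_rate = 0.2, n_docs = 100L,
                         mentions_per_doc = c(1L, 3L),
                         planted_pairs = NULL, pair_prob = 0.1,
                         zipf_exponent = 1.1, n_filler_words = 400L,
                         dag_extra_parent_prob = 0.15, seed = 1L) {
  stopifnot(n_concepts >= n_dimensions, max_depth >= 1L,
            length(branching) == 2L, branching[1] >= 1L,
            branching[2] >= branching[1], n_dimensions >= 1L,
            ambiguity_rate >= 0, ambiguity_rate <= 1, n_docs >= 1L,
            length(mentions_per_doc) == 2L, mentions_per_doc[1] >= 1L,
            pair_prob > 0, pair_prob < 0.5, zipf_exponent > 0,
            n_filler_words >= 10L)
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(a = character(0), b = character(0),
                                lift = numeric(0), stringsAsFactors = FALSE)
  }
  if (nrow(planted_pairs) > 0L && any(planted_pairs$lift < 1)) {
    stop("planted pair lift must be >= 1")
  }
  per_dim <- ceiling(n_concepts / n_dimensions)
  capacity <- sum(branching[2]^(0:max_depth))
  if (per_dim > capacity) {
    stop(sprintf(
      "infeasible config: %d concepts per dimension exceed capacity %d of a depth-%d, branching<=%d tree",
      per_dim, capacity, max_depth, branching[2]))
  }
  structure(list(
    n_concepts = as.integer(n_concepts), max_depth = as.integer(max_depth),
    branching = as.integer(branching), n_dimensions = as.integer(n_dimensions),
    ambiguity_rate = ambiguity_rate, n_docs = as.integer(n_docs),
    mentions_per_doc = as.integer(mentions_per_doc),
    planted_pairs = planted_pairs, pair_prob = pair_prob,
    zipf_exponent = zipf_exponent, n_filler_words = as.integer(n_filler_words),
    dag_extra_parent_prob = dag_extra_parent_prob, seed = as.integer(seed)),
    class = "semcube_synth_config")
}

filler_vocab <- function(config) {
  sprintf("filler%03d", seq_len(config$n_filler_words))
}

#' Generate a seeded synthetic ontology, dimension specs and background
#'
#' Builds `n_dimensions` disjoint rooted taxonomies (random trees plus
#' occasional extra parents, so the result is a proper DAG), one semantic
#' type per dimension, a lexicon of synthetic multiword variants — an
#' `ambiguity_rate` share of strings is attached to two concepts of
#' different dimensions — and a Zipfian background count table over the
#' filler vocabulary. Deterministic for a fixed seed.
#'
#' @param config A `semcube_synth_config`.
#' @return List with `ontology`, `specs` (dimension specs), `background`
#'   (a `semcube_background`), `background_counts` (named vector),
#'   `dim_of` (concept -> dimension name), `parent_of` (concept -> first
#'   parent), `ambiguous_strings` (data.frame string/concept_a/concept_b),
#'   `config`.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "semcube_synth_config"))
  set.seed(config$seed)
  n_dim <- config$n_dimensions
  dims <- sprintf("Dim%d", seq_len(n_dim))
  per_dim <- diff_round(config$n_concepts, n_dim)

  concepts <- list(); isa <- list(); dim_of <- character(0)
  parent_of <- character(0)
  counter <- 0L
  depth_of <- integer(0)
  for (d in seq_len(n_dim)) {
    n_d <- per_dim[d]
    ids <- sprintf("C%04d", counter + seq_len(n_d))
    counter <- counter + n_d
    depth <- stats::setNames(integer(n_d), ids)
    kids_count <- stats::setNames(integer(n_d), ids)
    for (k in seq_len(n_d)) {
      if (k == 1L) { depth[ids[k]] <- 0L; next }
      open <- ids[seq_len(k - 1L)]
      open <- open[depth[open] < config$max_depth &
                     kids_count[open] < config$branching[2]]
      if (length(open) == 0L) {
        stop("infeasible config: no open attachment point in dimension ", d)
      }
      par <- if (length(open) == 1L) open else sample(open, 1L)
      isa[[length(isa) + 1L]] <- c(ids[k], par)
      parent_of[ids[k]] <- par
      depth[ids[k]] <- depth[par] + 1L
      kids_count[par] <- kids_count[par] + 1L
      # occasional second parent (shallower, different node) -> DAG
      if (stats::runif(1) < config$dag_extra_parent_prob) {
        cand <- ids[seq_len(k - 1L)]
        cand <- cand[depth[cand] < depth[ids[k]] & cand != par]
        if (length(cand) > 0L) {
          par2 <- if (length(cand) == 1L) cand else sample(cand, 1L)
          isa[[length(isa) + 1L]] <- c(ids[k], par2)
        }
      }
    }
    concepts[[d]] <- data.frame(
      id = ids, label = paste("concept", tolower(ids)),
      semantic_types = sprintf("T%03d", d), source = "SYNTH",
      stringsAsFactors = FALSE)
    dim_of[ids] <- dims[d]
    depth_of[ids] <- depth[ids]
  }
  concepts <- do.call(rbind, concepts)
  isa_df <- if (length(isa) > 0L) {
    m <- do.call(rbind, isa)
    data.frame(child_id = m[, 1], parent_id = m[, 2], stringsAsFactors = FALSE)
  } else empty_isa()

  # lexicon: one unique variant per concept (1-2 tokens), plus ambiguous
  # strings shared by two concepts of different dimensions
  all_ids <- concepts$id
  lex <- data.frame(
    concept_id = all_ids,
    surface_string = sprintf("term %s", tolower(all_ids)),
    stringsAsFactors = FALSE)
  n_amb <- round(config$ambiguity_rate / max(1e-9, 1 - config$ambiguity_rate) *
                   length(all_ids))
  amb <- data.frame(string = character(0), concept_a = character(0),
                    concept_b = character(0), stringsAsFactors = FALSE)
  if (n_amb > 0L && n_dim >= 2L) {
    for (k in seq_len(n_amb)) {
      d_ab <- sample(seq_len(n_dim), 2L)
      a <- sample(all_ids[dim_of[all_ids] == dims[d_ab[1]]], 1L)
      b <- sample(all_ids[dim_of[all_ids] == dims[d_ab[2]]], 1L)
      s <- sprintf("amb%03d shared%03d", k, k)
      lex <- rbind(lex,
                   data.frame(concept_id = c(a, b), surface_string = s,
                              stringsAsFactors = FALSE))
      amb <- rbind(amb, data.frame(string = s, concept_a = a, concept_b = b,
                                   stringsAsFactors = FALSE))
    }
  }

  # a few named relations between random cross-dimension concepts
  n_rel <- max(1L, round(0.05 * length(all_ids)))
  rel <- data.frame(
    relation_name = rep("related_to", n_rel),
    source_id = sample(all_ids, n_rel, replace = TRUE),
    target_id = sample(all_ids, n_rel, replace = TRUE),
    stringsAsFactors = FALSE)
  rel <- rel[rel$source_id != rel$target_id, , drop = FALSE]

  onto <- ontology(concepts, isa_df, rel, lex)
  specs <- lapply(seq_len(n_dim), function(d) {
    dimension_spec(dims[d], priority = d,
                   semantic_types = sprintf("T%03d", d))
  })

  fv <- filler_vocab(config)
  counts <- pmax(1, round(1e6 * seq_along(fv)^(-config$zipf_exponent) /
                            sum(seq_along(fv)^(-config$zipf_exponent))))
  names(counts) <- fv
  list(ontology = onto, specs = specs,
       background = background_model(counts),
       background_counts = counts, dim_of = dim_of, parent_of = parent_of,
       depth_of = depth_of, ambiguous_strings = amb, config = config)
}

# split n into k near-equal positive parts
diff_round <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

# sample one Zipfian filler word sequence
sample_filler <- function(config, n) {
  fv <- filler_vocab(config)
  p <- seq_along(fv)^(-config$zipf_exponent)
  sample(fv, n, replace = TRUE, prob = p)
}

#' Generate a corpus with planted mentions and planted associations
#'
#' Each document mentions at most one concept per dimension. Planted pairs
#' drive their two dimensions: the pair co-occurs with probability
#' `lift * p^2` (p = `pair_prob`), each side alone with `p - lift * p^2`,
#' so the realized interest factor targets the configured lift while the
#' marginals stay at p. Remaining dimensions are sampled per
#' `mentions_per_doc`. Each mention is written as its own sentence: Zipfian
#' filler words around the chosen lexical variant. An ambiguous variant
#' (only used in dimensions untouched by planted pairs) is accompanied, in
#' the same sentence, by the unique variant of the intended sense's parent
#' concept, so the intended sense has affinity support and the decoy stays
#' isolated — disambiguation is solvable by construction.
#'
#' @param synth Output of [generate_ontology()].
#' @param config Optional `semcube_synth_config`; defaults to the one
#'   inside `synth`.
#' @return List with `docs` (data.frame id/text), `truth`: per-document
#'   planted facts (`facts`: doc -> named concept vector), mention records
#'   with character spans and intended senses (`mentions`), realized
#'   rolled-up pair counts (`pair_counts`), and `mean_ambiguity` (mean
#'   candidate count over ambiguous mentions, NA when none).
#' @export
generate_corpus <- function(synth, config = synth$config) {
  set.seed(config$seed + 1L)
  onto <- synth$ontology
  dims <- sort(unique(synth$dim_of))
  dim_members <- split(names(synth$dim_of), synth$dim_of)

  # resolve planted pairs; NA endpoints pick leaves of the first two dims
  pairs <- config$planted_pairs
  if (nrow(pairs) > 0L) {
    leaves <- setdiff(concept_ids(onto), onto$isa_edges$parent_id)
    for (i in seq_len(nrow(pairs))) {
      if (is.na(pairs$a[i])) {
        pairs$a[i] <- sample(intersect(leaves, dim_members[[dims[1]]]), 1L)
      }
      if (is.na(pairs$b[i])) {
        cand <- setdiff(intersect(leaves, dim_members[[dims[2]]]), pairs$b)
        pairs$b[i] <- sample(cand, 1L)
      }
    }
    p <- config$pair_prob
    for (i in seq_len(nrow(pairs))) {
      q <- pairs$lift[i] * p * p
      if (q > min(p, p)) {
        stop(sprintf(
          "lift %.2f unreachable at pair_prob %.3f; feasible maximum is %.2f",
          pairs$lift[i], p, 1 / p))
      }
    }
    pair_dims <- unique(c(synth$dim_of[pairs$a], synth$dim_of[pairs$b]))
  } else {
    pair_dims <- character(0)
  }
  free_dims <- setdiff(dims, pair_dims)
  amb <- synth$ambiguous_strings
  # ambiguous variants are only usable for concepts in free dimensions
  amb_by_concept <- list()
  if (nrow(amb) > 0L) {
    for (i in seq_len(nrow(amb))) {
      for (cid in c(amb$concept_a[i], amb$concept_b[i])) {
        if (synth$dim_of[cid] %in% free_dims &&
            !is.na(synth$parent_of[cid])) {
          amb_by_concept[[cid]] <- c(amb_by_concept[[cid]], amb$string[i])
        }
      }
    }
  }
  unique_variant <- function(cid) sprintf("term %s", tolower(cid))

  docs <- vector("list", config$n_docs)
  facts_truth <- list()
  mention_rows <- list()
  n_cand_amb <- integer(0)

  for (dnum in seq_len(config$n_docs)) {
    doc_id <- sprintf("doc%04d", dnum)
    assignment <- stats::setNames(rep(NA_character_, length(dims)), dims)
    # planted-pair dimensions
    if (nrow(pairs) > 0L) {
      p <- config$pair_prob
      for (i in seq_len(nrow(pairs))) {
        q <- pairs$lift[i] * p * p
        u <- stats::runif(1)
        has_a <- u < q || (u >= q && u < p)            # P(a) = p
        has_b <- u < q || (u >= p && u < 2 * p - q)    # P(b) = p, P(ab) = q
        if (has_a) assignment[synth$dim_of[pairs$a[i]]] <- pairs$a[i]
        if (has_b) assignment[synth$dim_of[pairs$b[i]]] <- pairs$b[i]
      }
      # pair dims not claimed stay possibly filled by an alternative concept
      for (dm in pair_dims) {
        if (is.na(assignment[dm]) && stats::runif(1) < 0.3) {
          alt <- setdiff(dim_members[[dm]], c(pairs$a, pairs$b))
          if (length(alt) > 0L) assignment[dm] <- sample(alt, 1L)
        }
      }
    }
    # free dimensions
    if (length(free_dims) > 0L) {
      lo <- config$mentions_per_doc[1]; hi <- config$mentions_per_doc[2]
      m <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
      m <- min(length(free_dims), m)
      chosen <- if (length(free_dims) == 1L) free_dims else
        sample(free_dims, m)
      for (dm in chosen) {
        assignment[dm] <- sample(dim_members[[dm]],
                                 1L)[[1]]
      }
    }

    # write one sentence per mentioned concept
    text <- ""
    for (dm in dims) {
      cid <- assignment[[dm]]
      if (is.na(cid)) next
      use_amb <- length(amb_by_concept[[cid]]) > 0L && stats::runif(1) < 0.6
      variant <- if (use_amb) {
        sample(amb_by_concept[[cid]], 1L)[[1]]
      } else {
        unique_variant(cid)
      }
      pre <- paste(sample_filler(config, sample(2:4, 1L)), collapse = " ")
      post <- paste(sample_filler(config, sample(1:3, 1L)), collapse = " ")
      sent <- paste0(pre, " ")
      if (nzchar(text)) sent <- paste0(" ", sent)
      start <- nchar(text) + nchar(sent)
      sent <- paste0(sent, variant)
      end <- nchar(text) + nchar(sent)
      if (use_amb) {
        support <- unique_variant(synth$parent_of[[cid]])
        sent <- paste0(sent, " ", paste(sample_filler(config, 2L),
                                        collapse = " "),
                       " ", support)
        n_cand_amb <- c(n_cand_amb, 2L)
      }
      sent <- paste0(sent, " ", post, ".")
      text <- paste0(text, sent)
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        doc_id = doc_id, concept = cid, dimension = dm, string = variant,
        start = start, end = end, ambiguous = use_amb,
        stringsAsFactors = FALSE)
    }
    docs[[dnum]] <- data.frame(id = doc_id, text = text,
                               stringsAsFactors = FALSE)
    facts_truth[[doc_id]] <- assignment
  }
  docs <- do.call(rbind, docs)
  mentions <- if (length(mention_rows) > 0L) do.call(rbind, mention_rows) else
    data.frame(doc_id = character(), concept = character(),
               dimension = character(), string = character(),
               start = integer(), end = integer(), ambiguous = logical(),
               stringsAsFactors = FALSE)

  # realized rolled-up pair counts via a traversal ancestor map
  pair_counts <- data.frame(a = character(), b = character(),
                            lift = numeric(), n_ij = integer(),
                            n_i = integer(), n_j = integer(), N = integer(),
                            stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    g <- ontology_graph(concept_ids(onto), onto$isa_edges)
    anc_of <- function(cid) names(igraph::subcomponent(g, cid, mode = "out"))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      da <- synth$dim_of[a]; db <- synth$dim_of[b]
      below_a <- vapply(facts_truth, function(f) {
        !is.na(f[[da]]) && a %in% anc_of(f[[da]])
      }, logical(1))
      below_b <- vapply(facts_truth, function(f) {
        !is.na(f[[db]]) && b %in% anc_of(f[[db]])
      }, logical(1))
      pair_counts <- rbind(pair_counts, data.frame(
        a = a, b = b, lift = pairs$lift[i],
        n_ij = sum(below_a & below_b), n_i = sum(below_a),
        n_j = sum(below_b), N = config$n_docs, stringsAsFactors = FALSE))
    }
  }
  list(docs = docs,
       truth = list(facts = facts_truth, mentions = mentions,
                    pair_counts = pair_counts,
                    mean_ambiguity = if (length(n_cand_amb) > 0L)
                      mean(n_cand_amb) else NA_real_))
}
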