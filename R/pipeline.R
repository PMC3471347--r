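#' Run the full normalization pipeline over a corpus
#'
#' Annotates every document, builds the per-document affinity matrix,
#' disambiguates, reduces each document to a multidimensional fact and
#' collects the facts into a store.
#'
#' @param docs data.frame with `id`, `text`.
#' @param onto Reference `semcube_ontology`.
#' @param schema A `semcube_schema` with levels (see [build_schema()]).
#' @param background A `semcube_background`.
#' @param index Interval index; built from `onto` when NULL.
#' @param alpha Smoothing parameter (default 0.9).
#' @param gamma Ancestor-term normalizer; default max taxonomy depth.
#' @param min_score,idf_mode Annotation parameters (see
#'   [annotate_chunk()]).
#' @return List with `store` (a `semcube_fact_store`), `annotations`
#'   (post-disambiguation, named by doc id), `raw_annotations`, `rejected`
#'   (per-doc rejection logs), `index`.
#' @export
normalize_corpus <- function(docs, onto, schema, background, index = NULL,
                             alpha = 0.9, gamma = NULL, min_score = 0.2,
                             idf_mode = "log") {
  if (is.null(index)) index <- build_interval_index(onto)
  if (is.null(gamma)) gamma <- max(1L, taxonomy_depth(onto))
  lex <- lexicon_index(onto)
  raw <- annotate_corpus(docs, lex, background, min_score, idf_mode)
  facts <- vector("list", nrow(docs))
  anns <- vector("list", nrow(docs))
  rejected <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    res <- normalize_document(raw[[i]], onto, index, schema,
                              alpha = alpha, gamma = gamma,
                              doc_id = docs$id[i])
    facts[[i]] <- res$fact
    anns[[i]] <- res$annotations
    rejected[[i]] <- res$rejected
  }
  names(anns) <- names(rejected) <- docs$id
  list(store = fact_store(facts, schema), annotations = anns,
       raw_annotations = raw, rejected = rejected, index = index)
}

#' Disambiguation accuracy against planted truth
#'
#' For every planted ambiguous mention, checks whether the surviving
#' candidate set of the annotation covering that span is exactly the
#' intended sense.
#'
#' @param annotations Named list (doc id -> post-disambiguation annotation
#'   data.frame), as returned by [normalize_corpus()].
#' @param truth Truth object from [generate_corpus()].
#' @return List with `accuracy` (NA when no ambiguous mentions), `n_cases`,
#'   `n_correct`.
#' @export
disambiguation_accuracy <- function(annotations, truth) {
  m <- truth$mentions[truth$mentions$ambiguous, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(list(accuracy = NA_real_, n_cases = 0L, n_correct = 0L))
  }
  correct <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ann <- annotations[[m$doc_id[i]]]
    if (is.null(ann) || nrow(ann) == 0L) next
    hit <- which(ann$start == m$start[i])
    if (length(hit) == 0L) next
    correct[i] <- identical(sort(ann$candidates[[hit[1]]]), m$concept[i])
  }
  list(accuracy = mean(correct), n_cases = nrow(m),
       n_correct = sum(correct))
}
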