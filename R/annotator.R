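#' Tokenize text into a token bag with offsets and sentence boundaries
#'
#' Tokens are maximal alphanumeric runs, lowercased; character offsets are
#' 0-based half-open into the original text. Sentence boundaries fall after
#' `.`, `!` or `?` followed by whitespace (or end of text).
#'
#' @param text A character scalar (UTF-8).
#' @return A list with `tokens` (lowercased, in order), `start`, `end`
#'   (integer offsets), `sentence` (1-based sentence index per token) and
#'   `n_sentences`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(list(tokens = character(0), start = integer(0), end = integer(0),
                sentence = integer(0), n_sentences = 0L))
  }
  ml <- gregexpr("[[:alnum:]]+", text)
  m <- ml[[1]]
  if (m[1] == -1L) {
    return(list(tokens = character(0), start = integer(0), end = integer(0),
                sentence = integer(0), n_sentences = 0L))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  toks <- tolower(regmatches(text, ml)[[1]])
  b <- gregexpr("[.!?](?=\\s|$)", text, perl = TRUE)[[1]]
  bpos <- if (b[1] == -1L) integer(0) else as.integer(b)
  sent <- vapply(start1, function(s) sum(bpos < s), integer(1)) + 1L
  list(tokens = toks, start = start1 - 1L, end = start1 - 1L + len,
       sentence = sent, n_sentences = max(sent))
}

#' Build a background word-frequency model
#'
#' Word probabilities p(w | Background) are counts normalized by the total;
#' unseen words receive a configurable floor probability so information
#' content stays finite.
#'
#' @param counts Named numeric vector (word -> count) or data.frame with
#'   columns `word`, `count`.
#' @param oov_probability Probability for out-of-vocabulary words; defaults
#'   to 1 / (10 * total count).
#' @return A `semcube_background` with fields `p` and `oov`.
#' @export
background_model <- function(counts, oov_probability = NULL) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(as.numeric(counts$count), counts$word)
  }
  if (any(counts <= 0)) stop("background counts must be positive")
  total <- sum(counts)
  p <- counts / total
  if (is.null(oov_probability)) oov_probability <- 1 / (10 * total)
  if (oov_probability <= 0) stop("oov_probability must be > 0")
  structure(list(p = p, oov = oov_probability), class = "semcube_background")
}

word_prob <- function(background, words) {
  p <- background$p[words]
  p[is.na(p)] <- background$oov
  unname(p)
}

#' Information content of a token bag
#'
#' Default (`mode = "log"`) sums the negative log-probability of each token
#' under the background model, the Shannon information of the bag. Mode
#' `"linear"` returns the negated raw probability sum instead (a flat
#' variant kept for fidelity experiments; note it is negative).
#'
#' @param tokens Character vector of tokens (a bag: multiplicity counts).
#' @param background A `semcube_background`.
#' @param mode `"log"` (default) or `"linear"`.
#' @return Numeric scalar; 0 for the empty bag.
#' @export
information_content <- function(tokens, background, mode = c("log", "linear")) {
  mode <- match.arg(mode)
  if (length(tokens) == 0L) return(0)
  p <- word_prob(background, tokens)
  if (any(p <= 0)) stop("background probabilities must be > 0")
  if (mode == "log") sum(-log(p)) else -sum(p)
}

# multiset difference S \ T and intersection size |S ∩ T|
bag_diff <- function(s, t) {
  for (w in t) {
    i <- match(w, s)
    if (!is.na(i)) s <- s[-i]
  }
  s
}
bag_intersect_size <- function(s, t) length(s) - length(bag_diff(s, t))

#' Build a lexicon index from an ontology's lexicon
#'
#' Indexes each surface string's token bag, its candidate concept set
#' (`ambiguity(S)` = number of concepts carrying S as a lexical variant),
#' and an inverted token -> string map for candidate generation.
#'
#' @param onto A `semcube_ontology` with a non-empty lexicon.
#' @return A `semcube_lexicon` with fields `strings`, `bags`, `concepts`,
#'   `inverted`.
#' @export
lexicon_index <- function(onto) {
  stopifnot(inherits(onto, "semcube_ontology"))
  lex <- onto$lexicon
  if (nrow(lex) == 0L) stop("ontology has an empty lexicon")
  strings <- sort(unique(lex$surface_string))
  bags <- lapply(strings, function(s) tokenize(s)$tokens)
  concepts <- lapply(strings, function(s) {
    sort(unique(lex$concept_id[lex$surface_string == s]))
  })
  names(bags) <- names(concepts) <- strings
  pairs <- data.frame(
    token = unlist(bags, use.names = FALSE),
    string = rep(strings, vapply(bags, length, integer(1))),
    stringsAsFactors = FALSE)
  inverted <- lapply(split(pairs$string, pairs$token), unique)
  structure(list(strings = strings, bags = bags, concepts = concepts,
                 inverted = inverted),
            class = "semcube_lexicon")
}

#' @export
print.semcube_lexicon <- function(x, ...) {
  cat(sprintf("<semcube_lexicon> %d strings, %d concepts\n",
              length(x$strings), length(unique(unlist(x$concepts)))))
  invisible(x)
}

#' Rank a lexicon string against a text chunk
#'
#' The dictionary-lookup ranking: with `idf` the information content of a
#' bag, the score is
#' `((idf(S) - idf(S \ T)) / idf(S)) * |S ∩ T| / ambiguity(S)`
#' where S and T are bags of words and ambiguity(S) is the number of
#' concepts carrying S as a lexical variant. High-information, long,
#' unambiguous matches score highest; `idf(S) = 0` yields 0.
#'
#' @param s_tokens Token bag of the lexicon string S.
#' @param t_tokens Token bag of the text chunk T.
#' @param ambiguity Number of concepts with S as lexical variant (>= 1).
#' @param background A `semcube_background`.
#' @param idf_mode `"log"` or `"linear"` (see [information_content()]).
#' @return Numeric score in `[0, |S|]` for log mode.
#' @export
rank_candidate <- function(s_tokens, t_tokens, ambiguity, background,
                           idf_mode = c("log", "linear")) {
  idf_mode <- match.arg(idf_mode)
  stopifnot(ambiguity >= 1)
  idf_s <- information_content(s_tokens, background, idf_mode)
  if (idf_s == 0) return(0)
  idf_miss <- information_content(bag_diff(s_tokens, t_tokens), background,
                                  idf_mode)
  overlap <- bag_intersect_size(s_tokens, t_tokens)
  ((idf_s - idf_miss) / idf_s) * overlap / ambiguity
}

# occurrences of string tokens `sq` in sentence tokens `st`:
# contiguous runs first; if none, one non-contiguous fallback over S ∩ T.
find_occurrences <- function(sq, st) {
  k <- length(sq); n <- length(st)
  occ <- list()
  if (k <= n) {
    for (i in seq_len(n - k + 1L)) {
      if (all(st[i:(i + k - 1L)] == sq)) {
        occ[[length(occ) + 1L]] <- i:(i + k - 1L)
      }
    }
  }
  if (length(occ) == 0L) {
    pos <- integer(0)
    used <- logical(n)
    for (w in sq) {
      j <- which(st == w & !used)
      if (length(j) > 0L) {
        pos <- c(pos, j[1]); used[j[1]] <- TRUE
      }
    }
    if (length(pos) > 0L) occ[[1L]] <- sort(pos)
  }
  occ
}

#' Annotate one text chunk with lexicon concepts (greedy cover)
#'
#' Candidate strings are those sharing at least one token with the chunk;
#' each is scored with [rank_candidate()] and its occurrences located.
#' Matches are accepted in descending score order (ties: longer match, then
#' lexicographic string, then leftmost) provided the score reaches
#' `min_score` and none of the match's token positions is already covered,
#' so no token position is ever covered twice. An accepted match emits one
#' annotation carrying *every* concept that has the string as lexical
#' variant — ambiguity is preserved for the disambiguation stage.
#'
#' @param chunk_tokens Tokenization of the chunk (a sentence), as returned
#'   by [tokenize()] restricted to the chunk, plus `sentence_index`.
#' @param lexicon A `semcube_lexicon`.
#' @param background A `semcube_background`.
#' @param min_score Minimum accepted rank score (default 0.2).
#' @param idf_mode Passed to [rank_candidate()].
#' @param doc_id Document id stamped on the annotations.
#' @param sentence_index Sentence number stamped on the annotations.
#' @return data.frame with columns `doc_id`, `start`, `end`, `string`,
#'   `score`, `sentence`, `ambiguous`, and list-column `candidates`.
#' @export
annotate_chunk <- function(chunk_tokens, lexicon, background, min_score = 0.2,
                           idf_mode = "log", doc_id = "doc",
                           sentence_index = 1L) {
  st <- chunk_tokens$tokens
  if (length(st) == 0L) return(empty_annotations())
  cand <- unique(unlist(lexicon$inverted[unique(st)], use.names = FALSE))
  if (length(cand) == 0L) return(empty_annotations())

  rows <- list()
  for (s in cand) {
    sq <- lexicon$bags[[s]]
    score <- rank_candidate(sq, st, length(lexicon$concepts[[s]]),
                            background, idf_mode)
    if (score < min_score) next
    for (pos in find_occurrences(sq, st)) {
      rows[[length(rows) + 1L]] <- list(string = s, score = score, pos = pos)
    }
  }
  if (length(rows) == 0L) return(empty_annotations())
  len <- vapply(rows, function(r) length(r$pos), integer(1))
  first <- vapply(rows, function(r) r$pos[1], integer(1))
  strs <- vapply(rows, function(r) r$string, character(1))
  scr <- vapply(rows, function(r) r$score, numeric(1))
  ord <- order(-scr, -len, strs, first)

  covered <- logical(length(st))
  out <- list()
  for (i in ord) {
    pos <- rows[[i]]$pos
    if (any(covered[pos])) next
    covered[pos] <- TRUE
    cids <- lexicon$concepts[[rows[[i]]$string]]
    out[[length(out) + 1L]] <- data.frame(
      doc_id = doc_id,
      start = chunk_tokens$start[min(pos)],
      end = chunk_tokens$end[max(pos)],
      string = rows[[i]]$string,
      score = rows[[i]]$score,
      sentence = as.integer(sentence_index),
      ambiguous = length(cids) > 1L,
      stringsAsFactors = FALSE)
    out[[length(out)]]$candidates <- list(cids)
  }
  ann <- do.call(rbind, out)
  ann[order(ann$start), , drop = FALSE]
}

empty_annotations <- function() {
  ann <- data.frame(doc_id = character(), start = integer(), end = integer(),
                    string = character(), score = numeric(),
                    sentence = integer(), ambiguous = logical(),
                    stringsAsFactors = FALSE)
  ann$candidates <- list()
  ann
}

#' Annotate a whole document sentence by sentence
#'
#' Chunks are sentences; each is annotated independently with
#' [annotate_chunk()] and the results concatenated in document order.
#'
#' @param doc_id Document id.
#' @param text Document text.
#' @param lexicon A `semcube_lexicon`.
#' @param background A `semcube_background`.
#' @param min_score,idf_mode See [annotate_chunk()].
#' @return Annotation data.frame (see [annotate_chunk()]).
#' @export
annotate_document <- function(doc_id, text, lexicon, background,
                              min_score = 0.2, idf_mode = "log") {
  tk <- tokenize(text)
  if (length(tk$tokens) == 0L) return(empty_annotations())
  out <- lapply(seq_len(tk$n_sentences), function(si) {
    sel <- tk$sentence == si
    chunk <- list(tokens = tk$tokens[sel], start = tk$start[sel],
                  end = tk$end[sel])
    annotate_chunk(chunk, lexicon, background, min_score, idf_mode,
                   doc_id = doc_id, sentence_index = si)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate a corpus
#'
#' @param docs data.frame with columns `id`, `text` (as from
#'   [read_corpus()]).
#' @param lexicon,background,min_score,idf_mode See [annotate_document()].
#' @return Named list of annotation data.frames, one per document id.
#' @export
annotate_corpus <- function(docs, lexicon, background, min_score = 0.2,
                            idf_mode = "log") {
  out <- lapply(seq_len(nrow(docs)), function(i) {
    annotate_document(docs$id[i], docs$text[i], lexicon, background,
                      min_score, idf_mode)
  })
  names(out) <- docs$id
  out
}
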