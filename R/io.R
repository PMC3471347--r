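#' Parse a concept cross-reference string
#'
#' A cross-reference has three colon-separated parts:
#' `source:concept_id:semantic_type` (e.g. `"UMLS:C0007457:T098"`). The
#' split happens on the first two colons, so semantic types containing
#' colons survive.
#'
#' @param s Non-empty character scalar.
#' @return List with `source`, `concept_id`, `semantic_type`.
#' @export
parse_crossref <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3L || any(!nzchar(parts[1:2]))) {
    stop("malformed cross-reference (need source:concept:semtype): '", s, "'")
  }
  semtype <- paste(parts[-(1:2)], collapse = ":")
  if (!nzchar(semtype)) {
    stop("malformed cross-reference (need source:concept:semtype): '", s, "'")
  }
  list(source = parts[1], concept_id = parts[2], semantic_type = semtype)
}

#' Serialize a cross-reference
#' @param x List with `source`, `concept_id`, `semantic_type`.
#' @return `"source:concept_id:semantic_type"`.
#' @export
format_crossref <- function(x) {
  paste(x$source, x$concept_id, x$semantic_type, sep = ":")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# cross-reference for one candidate concept, looked up in the ontology
concept_crossref <- function(onto, cid) {
  i <- match(cid, onto$concepts$id)
  src <- if (is.na(i) || !nzchar(onto$concepts$source[i])) "LOCAL" else
    onto$concepts$source[i]
  st <- if (is.na(i)) character(0) else
    strsplit(onto$concepts$semantic_types[i], "|", fixed = TRUE)[[1]]
  st <- st[nzchar(st)]
  st <- if (length(st) == 0L) "T000" else st[1]
  paste(src, cid, st, sep = ":")
}

#' Write a document with inline XML annotations
#'
#' Emits the inline-annotation dialect: the text wrapped in a `doc` element,
#' with each annotated mention wrapped in an `e` element whose `id`
#' attribute holds the semicolon-joined cross-references of all candidate
#' concepts. Stripping the tags recovers the original text byte for byte.
#'
#' @param doc_id Document id (stamped on the `doc` element).
#' @param text Original document text.
#' @param annotations Annotation data.frame (spans must be within the text
#'   and non-overlapping).
#' @param onto The ontology, used to resolve each candidate's source and
#'   semantic type.
#' @return XML string.
#' @export
write_iexml <- function(doc_id, text, annotations, onto) {
  if (nrow(annotations) > 0L) {
    ann <- annotations[order(annotations$start), , drop = FALSE]
    if (any(ann$start < 0 | ann$end > nchar(text))) {
      stop("annotation span outside document")
    }
    if (nrow(ann) > 1L && any(ann$start[-1L] < ann$end[-nrow(ann)])) {
      stop("overlapping annotation spans")
    }
  } else {
    ann <- annotations
  }
  parts <- character(0)
  cursor <- 0L
  for (k in seq_len(nrow(ann))) {
    s <- ann$start[k]; e <- ann$end[k]
    if (s > cursor) {
      parts <- c(parts, xml_escape(substr(text, cursor + 1L, s)))
    }
    refs <- vapply(ann$candidates[[k]], function(cid) {
      concept_crossref(onto, cid)
    }, character(1))
    parts <- c(parts,
               sprintf('<e id="%s">%s</e>',
                       xml_escape(paste(refs, collapse = ";")),
                       xml_escape(substr(text, s + 1L, e))))
    cursor <- e
  }
  if (cursor < nchar(text)) {
    parts <- c(parts, xml_escape(substr(text, cursor + 1L, nchar(text))))
  }
  sprintf('<doc id="%s">%s</doc>', xml_escape(doc_id),
          paste(parts, collapse = ""))
}

#' Parse an inline-XML annotated document
#'
#' Inverse of [write_iexml()]: recovers the document id, the raw text, and
#' the annotations (span, matched string, candidate concept ids from the
#' cross-references).
#'
#' @param xml XML string produced by [write_iexml()].
#' @return List with `doc_id`, `text`, `annotations` (data.frame with
#'   `start`, `end`, `string`, list-column `candidates`, and `crossrefs`).
#' @export
parse_iexml <- function(xml) {
  # keep whitespace-only text nodes (the default NOBLANKS would drop a
  # bare space between two adjacent mentions)
  doc <- xml2::read_xml(xml, options = character(0))
  doc_id <- xml2::xml_attr(doc, "id")
  text <- ""
  rows <- list()
  for (node in xml2::xml_contents(doc)) {
    if (xml2::xml_type(node) == "text") {
      text <- paste0(text, xml2::xml_text(node))
    } else if (xml2::xml_name(node) == "e") {
      mention <- xml2::xml_text(node)
      start <- nchar(text)
      text <- paste0(text, mention)
      refs <- strsplit(xml2::xml_attr(node, "id"), ";", fixed = TRUE)[[1]]
      cands <- vapply(refs, function(r) parse_crossref(r)$concept_id,
                      character(1))
      rows[[length(rows) + 1L]] <- list(
        start = start, end = nchar(text), string = mention,
        candidates = sort(unname(cands)), crossrefs = refs)
    }
  }
  ann <- if (length(rows) > 0L) {
    df <- data.frame(
      start = vapply(rows, `[[`, integer(1), "start"),
      end = vapply(rows, `[[`, integer(1), "end"),
      string = vapply(rows, `[[`, character(1), "string"),
      stringsAsFactors = FALSE)
    df$candidates <- lapply(rows, `[[`, "candidates")
    df$crossrefs <- lapply(rows, `[[`, "crossrefs")
    df
  } else {
    df <- data.frame(start = integer(), end = integer(), string = character(),
                     stringsAsFactors = FALSE)
    df$candidates <- list(); df$crossrefs <- list()
    df
  }
  list(doc_id = doc_id, text = text, annotations = ann)
}

read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "#")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Read an ontology from its flat TSV directory
#'
#' Expects `concepts.tsv` (id, label, semantic_types, source), `isa.tsv`
#' (child_id, parent_id), and optionally `relations.tsv` (relation_name,
#' source_id, target_id) and `lexicon.tsv` (concept_id, surface_string).
#'
#' @param dir Directory path.
#' @return A `semcube_ontology`.
#' @export
read_ontology <- function(dir) {
  concepts <- read_tsv(file.path(dir, "concepts.tsv"),
                       c("id", "label", "semantic_types", "source"))
  isa <- if (file.exists(file.path(dir, "isa.tsv"))) {
    read_tsv(file.path(dir, "isa.tsv"), c("child_id", "parent_id"))
  } else empty_isa()
  rel <- if (file.exists(file.path(dir, "relations.tsv"))) {
    read_tsv(file.path(dir, "relations.tsv"),
             c("relation_name", "source_id", "target_id"))
  } else empty_relations()
  lex <- if (file.exists(file.path(dir, "lexicon.tsv"))) {
    lx <- read_tsv(file.path(dir, "lexicon.tsv"),
                   c("concept_id", "surface_string"))
    dup <- duplicated(paste(lx$concept_id, lx$surface_string, sep = "\r"))
    if (any(dup)) {
      stop(file.path(dir, "lexicon.tsv"), ": duplicate row(s) at line(s) ",
           paste(which(dup) + 1L, collapse = ", "))
    }
    lx
  } else empty_lexicon()
  ontology(concepts, isa, rel, lex)
}

#' Write an ontology to a flat TSV directory
#'
#' Deterministic inverse of [read_ontology()]: rows are written in sorted
#' order so outputs are diffable across runs.
#'
#' @param onto A `semcube_ontology`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ontology <- function(onto, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- onto$concepts[order(onto$concepts$id), , drop = FALSE]
  write_tsv(co, file.path(dir, "concepts.tsv"))
  isa <- onto$isa_edges[order(onto$isa_edges$child_id,
                              onto$isa_edges$parent_id), , drop = FALSE]
  write_tsv(isa, file.path(dir, "isa.tsv"))
  rel <- onto$relations[order(onto$relations$relation_name,
                              onto$relations$source_id,
                              onto$relations$target_id), , drop = FALSE]
  write_tsv(rel, file.path(dir, "relations.tsv"))
  lex <- onto$lexicon[order(onto$lexicon$concept_id,
                            onto$lexicon$surface_string), , drop = FALSE]
  write_tsv(lex, file.path(dir, "lexicon.tsv"))
  invisible(dir)
}

#' Read a document collection
#'
#' JSONL mode (`path` is a file): one JSON object `{id, text}` per line.
#' Directory mode (`path` is a directory): every `*.txt` file becomes a
#' document with its filename (sans extension) as id.
#'
#' @param path JSONL file or directory of `.txt` files.
#' @return data.frame with columns `id`, `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    docs <- data.frame(
      id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
              collapse = "\n")
      }, character(1)),
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$id) || is.null(rec$text)) {
        stop(path, ":", i, ": malformed corpus record")
      }
      rec
    })
    docs <- data.frame(
      id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(docs$id)) {
    stop("duplicate document id(s): ",
         paste(unique(docs$id[duplicated(docs$id)]), collapse = ", "))
  }
  docs
}

#' Write a corpus as JSONL
#' @param docs data.frame with `id`, `text`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(list(id = docs$id[i], text = docs$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp, useBytes = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a background word-frequency table
#'
#' `background.tsv` has columns `word`, `count`; probabilities are counts
#' over the total with the out-of-vocabulary floor of [background_model()].
#'
#' @param path TSV file.
#' @param oov_probability See [background_model()].
#' @return A `semcube_background`.
#' @export
read_background <- function(path, oov_probability = NULL) {
  df <- read_tsv(path, c("word", "count"))
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt))) {
    stop(path, ": non-numeric count at line(s) ",
         paste(which(is.na(cnt)) + 1L, collapse = ", "))
  }
  background_model(stats::setNames(cnt, df$word), oov_probability)
}

#' Write a background table
#' @param counts Named numeric vector (word -> count).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_background <- function(counts, path) {
  df <- data.frame(word = names(counts), count = unname(counts),
                   stringsAsFactors = FALSE)
  write_tsv(df[order(df$word), , drop = FALSE], path)
}

#' Read a dimension configuration
#'
#' JSON list of `{name, priority, semantic_types, roots}` objects.
#'
#' @param path JSON file.
#' @return List of `semcube_dimension_spec`.
#' @export
read_dimension_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(cfg, function(x) {
    dimension_spec(x$name, x$priority,
                   semantic_types = as.character(x$semantic_types %||% character(0)),
                   roots = as.character(x$roots %||% character(0)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export schema levels as a flat table
#' @param schema A `semcube_schema` with levels.
#' @param path Output TSV (`dimension`, `depth`, `concept_id`).
#' @return `path`, invisibly.
#' @export
write_levels <- function(schema, path) {
  rows <- list()
  for (nm in names(schema$levels)) {
    for (l in schema$levels[[nm]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = nm, depth = l$depth, concept_id = l$members,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  write_tsv(df, path)
}

#' Flatten annotations for TSV export
#'
#' One row per (annotation, candidate) pair.
#'
#' @param annotations Annotation data.frame with the `candidates`
#'   list-column.
#' @return data.frame with `doc_id`, `start`, `end`, `string`,
#'   `concept_id`, `score`, `ambiguous`, `sentence`.
#' @export
flatten_annotations <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), string = character(),
                      concept_id = character(), score = numeric(),
                      ambiguous = logical(), sentence = integer(),
                      stringsAsFactors = FALSE))
  }
  k <- vapply(annotations$candidates, length, integer(1))
  data.frame(
    doc_id = rep(annotations$doc_id, k),
    start = rep(annotations$start, k),
    end = rep(annotations$end, k),
    string = rep(annotations$string, k),
    concept_id = unlist(annotations$candidates),
    score = rep(annotations$score, k),
    ambiguous = rep(annotations$ambiguous, k),
    sentence = rep(annotations$sentence, k),
    stringsAsFactors = FALSE)
}

#' Export a fact store as a flat table
#' @param store A `semcube_fact_store`.
#' @param path Output TSV (`doc_id`, `dimension`, `concept_id`, `score`);
#'   null assignments are written as the literal `NULL`.
#' @return `path`, invisibly.
#' @export
write_facts <- function(store, path) {
  rows <- list()
  for (f in store$facts) {
    for (nm in names(f$assignment)) {
      cid <- f$assignment[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = f$doc_id, dimension = nm,
        concept_id = if (is.na(cid)) "NULL" else cid,
        score = if (is.na(cid)) NA_real_ else unname(f$rank_vector[cid]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$doc_id, df$dimension), , drop = FALSE]
  write_tsv(df, path)
}
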