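#' Read a tokenized corpus
#'
#' Reads a corpus of short documents stored one document per line, tokens
#' separated by whitespace, optionally paired with a label file holding one
#' integer class label per line (used for evaluation only, never during
#' training). Documents shorter than `min_tokens` are dropped with a message.
#'
#' @param tokens_path Path to the UTF-8 token file, one document per line.
#' @param labels_path Optional path to a parallel label file, one base-10
#'   integer per line; line counts must match `tokens_path`.
#' @param min_tokens Minimum token count; shorter documents are dropped.
#' @param lowercase Lowercase all tokens on load (default keeps case).
#' @return A corpus tibble with columns `doc_id` (character), `tokens`
#'   (list of character vectors) and `label` (integer, `NA` when unlabeled).
#' @examples
#' tf <- tempfile()
#' writeLines(c("liver pain night", "diet after surgery"), tf)
#' read_corpus(tf)
#' @export
read_corpus <- function(tokens_path, labels_path = NULL, min_tokens = 1L,
                        lowercase = FALSE) {
  if (!file.exists(tokens_path)) {
    abort(paste0("token file not found: ", tokens_path))
  }
  lines <- readLines(tokens_path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) {
    abort("empty corpus: token file has no lines")
  }
  labels <- rep(NA_integer_, length(lines))
  if (!is.null(labels_path)) {
    lab_lines <- readLines(labels_path, encoding = "UTF-8", warn = FALSE)
    if (length(lab_lines) != length(lines)) {
      abort(sprintf(
        "label alignment error: %d documents but %d labels",
        length(lines), length(lab_lines)
      ))
    }
    labels <- suppressWarnings(as.integer(lab_lines))
    if (anyNA(labels)) {
      bad <- which(is.na(labels))[1]
      abort(sprintf("label parse error at line %d: '%s'", bad, lab_lines[bad]))
    }
  }
  if (lowercase) lines <- tolower(lines)
  toks <- strsplit(trimws(lines), "\\s+")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  keep <- lengths(toks) >= max(1L, min_tokens)
  if (sum(!keep) > 0) {
    inform(sprintf("dropped %d document(s) shorter than %d token(s)",
                   sum(!keep), min_tokens))
  }
  if (!any(keep)) abort("empty corpus: no document meets min_tokens")
  corpus <- tibble(
    doc_id = sprintf("doc%d", seq_along(lines))[keep],
    tokens = toks[keep],
    label = labels[keep]
  )
  validate_corpus(corpus)
}

#' Write a corpus back to token (and label) files
#'
#' Inverse of [read_corpus()]: one document per line, tokens joined by single
#' spaces; labels, when present, one integer per line in document order.
#'
#' @param corpus A corpus tibble.
#' @param tokens_path Output token file path.
#' @param labels_path Optional output label file path (required if the corpus
#'   carries labels and you want them persisted).
#' @return `corpus`, invisibly.
#' @export
write_corpus <- function(corpus, tokens_path, labels_path = NULL) {
  corpus <- validate_corpus(corpus)
  writeLines(vapply(corpus$tokens, paste, "", collapse = " "), tokens_path,
             useBytes = TRUE)
  if (!is.null(labels_path)) {
    if (anyNA(corpus$label)) abort("corpus has no complete labels to write")
    writeLines(as.character(corpus$label), labels_path)
  }
  invisible(corpus)
}

# Check the corpus contract: unique doc ids, non-empty token vectors,
# integer (possibly all-NA) labels.
validate_corpus <- function(corpus) {
  if (!all(c("doc_id", "tokens") %in% names(corpus))) {
    abort("a corpus needs 'doc_id' and 'tokens' columns")
  }
  if (anyDuplicated(corpus$doc_id)) abort("doc_ids must be unique")
  if (any(lengths(corpus$tokens) == 0)) abort("empty documents are not allowed")
  if (!"label" %in% names(corpus)) corpus$label <- NA_integer_
  corpus$label <- as.integer(corpus$label)
  if (nrow(corpus) == 0) abort("empty corpus")
  as_tibble(corpus)
}

corpus_has_labels <- function(corpus) !anyNA(corpus$label)

#' Build a vocabulary with document frequencies
#'
#' Words occurring in at least `min_doc_freq` documents are retained, ordered
#' by descending document frequency with ties broken lexicographically, so the
#' vocabulary (and everything indexed by it) is deterministic.
#'
#' @param corpus A corpus tibble.
#' @param min_doc_freq Minimum number of documents a word must appear in.
#' @return A tibble with columns `word`, `doc_freq`, `index` (1-based) and
#'   attribute `n_docs`, the corpus size N used by the idf formula.
#' @examples
#' corp <- tibble::tibble(doc_id = c("a", "b"),
#'                        tokens = list(c("a", "b"), c("a", "c")),
#'                        label = NA_integer_)
#' build_vocabulary(corp)
#' @export
build_vocabulary <- function(corpus, min_doc_freq = 1L) {
  corpus <- validate_corpus(corpus)
  if (min_doc_freq < 1) abort("min_doc_freq must be >= 1")
  df <- table(unlist(lapply(corpus$tokens, unique), use.names = FALSE))
  df <- df[df >= min_doc_freq]
  if (length(df) == 0) abort("vocabulary empty after min_doc_freq filtering")
  ord <- order(-as.integer(df), names(df), method = "radix")
  vocab <- tibble(
    word = names(df)[ord],
    doc_freq = as.integer(df)[ord],
    index = seq_along(df)
  )
  attr(vocab, "n_docs") <- nrow(corpus)
  vocab
}
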