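#' Boundary-marked character n-grams of a word
#'
#' Wraps the word in begin/end markers `<` and `>` and returns every
#' contiguous length-`n` substring of the marked string, in order. These are
#' the subword units whose vectors sum to the word's vector, letting unseen
#' words still be embedded.
#'
#' @param word A non-empty string.
#' @param n n-gram length (>= 1).
#' @return Character vector of n-grams, e.g. `subword_ngrams("ab", 2)` gives
#'   `c("<a", "ab", "b>")`.
#' @export
subword_ngrams <- function(word, n) {
  if (!nzchar(word)) abort("word must be non-empty")
  if (n < 1) abort("n must be >= 1")
  marked <- paste0("<", word, ">")
  len <- nchar(marked)
  if (n >= len) return(marked)
  substring(marked, seq_len(len - n + 1), seq(n, len))
}

new_embedding_table <- function(words, vectors, subword_n = NULL,
                                ngram_vectors = NULL) {
  rownames(vectors) <- words
  structure(
    list(dim = ncol(vectors), words = words, vectors = vectors,
         subword_n = subword_n, ngram_vectors = ngram_vectors),
    class = "dsc_embeddings"
  )
}

#' @export
print.dsc_embeddings <- function(x, ...) {
  cat(sprintf("<dsc_embeddings: %d words, dim %d%s>\n",
              length(x$words), x$dim,
              if (is.null(x$subword_n)) "" else
                sprintf(", subword n=%d (%d n-grams)", x$subword_n,
                        nrow(x$ngram_vectors))))
  invisible(x)
}

#' Train word embeddings on a corpus
#'
#' Skip-gram with negative sampling in which a word's input representation is
#' the sum of its piece vectors: the word itself plus (when `subword_n` is
#' set) its boundary-marked character n-grams, so out-of-vocabulary words can
#' later be composed from known n-grams. A `method = "random"` mode draws
#' seeded random normal piece vectors under the identical composition
#' contract; it is useful when only the shapes and determinism matter.
#'
#' @param corpus A corpus tibble.
#' @param dim Embedding dimension (>= 2).
#' @param subword_n Optional n-gram length for subword composition.
#' @param window Maximum skip-gram window (actual window is sampled 1..window
#'   per position).
#' @param epochs Training passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param lr Initial learning rate, linearly decayed.
#' @param seed Integer seed; training is single-threaded and deterministic.
#' @param method `"sgns"` (trained) or `"random"` (seeded random vectors).
#' @return A `dsc_embeddings` table.
#' @export
train_embeddings <- function(corpus, dim, subword_n = NULL, window = 5L,
                             epochs = 15L, negative = 5L, lr = 0.05,
                             seed = 1L, method = c("sgns", "random")) {
  method <- match.arg(method)
  corpus <- validate_corpus(corpus)
  if (dim < 2) abort("dim must be >= 2")
  vocab <- build_vocabulary(corpus)
  words <- vocab$word
  n_words <- length(words)

  ngrams <- character()
  pieces <- as.list(seq_len(n_words) - 1L)
  if (!is.null(subword_n)) {
    per_word <- lapply(words, subword_ngrams, n = subword_n)
    ngrams <- sort(unique(unlist(per_word, use.names = FALSE)), method = "radix")
    pieces <- lapply(seq_len(n_words), function(i) {
      c(i - 1L, n_words - 1L + match(per_word[[i]], ngrams))
    })
  }
  n_pieces <- n_words + length(ngrams)

  if (method == "random") {
    piece_vecs <- with_seed(stage_seed(seed, "embeddings"), {
      matrix(rnorm(n_pieces * dim, sd = 1 / sqrt(dim)), n_pieces, dim)
    })
  } else {
    docs <- lapply(corpus$tokens, function(tk) match(tk, words) - 1L)
    freq <- as.numeric(table(factor(unlist(corpus$tokens, use.names = FALSE),
                                    levels = words)))
    piece_vecs <- sgns_train_cpp(docs, pieces, n_pieces, as.integer(dim),
                                 as.integer(window), as.integer(epochs),
                                 as.integer(negative), lr, freq,
                                 as.integer(stage_seed(seed, "embeddings")))
  }

  word_vecs <- t(vapply(pieces, function(ids) {
    colSums(piece_vecs[ids + 1L, , drop = FALSE])
  }, numeric(dim)))
  ngram_vecs <- NULL
  if (!is.null(subword_n)) {
    ngram_vecs <- piece_vecs[n_words + seq_along(ngrams), , drop = FALSE]
    rownames(ngram_vecs) <- ngrams
  }
  new_embedding_table(words, word_vecs, subword_n, ngram_vecs)
}

#' Look up (or compose) embedding vectors for tokens
#'
#' Known words use their table vector. Unknown words compose as the sum of
#' their known n-gram vectors when the table carries subword information, and
#' fall back to the zero vector otherwise — consistent with giving
#' uninformative words no weight downstream.
#'
#' @param table A `dsc_embeddings` table.
#' @param tokens Character vector of tokens.
#' @return A `length(tokens) x dim` matrix.
#' @export
embedding_vectors <- function(table, tokens) {
  out <- matrix(0, length(tokens), table$dim)
  idx <- match(tokens, table$words)
  known <- !is.na(idx)
  if (any(known)) out[known, ] <- table$vectors[idx[known], , drop = FALSE]
  if (!is.null(table$subword_n) && any(!known)) {
    for (i in which(!known)) {
      ng <- subword_ngrams(tokens[i], table$subword_n)
      hit <- match(ng, rownames(table$ngram_vectors))
      hit <- hit[!is.na(hit)]
      if (length(hit) > 0) {
        out[i, ] <- colSums(table$ngram_vectors[hit, , drop = FALSE])
      }
    }
  }
  rownames(out) <- tokens
  out
}

#' Read a plain-text word-vector table
#'
#' Parses the de facto word2vec text format: a header line
#' `"vocab_size dim"`, then one `word v1 ... vD` row per line. Duplicate
#' words keep the last occurrence (with a message); a row whose value count
#' does not match the declared dimension is a format error naming the line.
#'
#' @param path File path.
#' @return A `dsc_embeddings` table (no subword information).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1) abort("empty embedding file")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) abort("embedding header must be 'vocab_size dim'")
  n_decl <- as.integer(header[1])
  dim <- as.integer(header[2])
  if (is.na(n_decl) || is.na(dim)) abort("non-numeric embedding header")
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != n_decl) {
    warn(sprintf("header declares %d words but file has %d rows",
                 n_decl, length(rows)))
  }
  words <- character(length(rows))
  vecs <- matrix(NA_real_, length(rows), dim)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != dim + 1) {
      abort(sprintf("format error at line %d: %d values for dim %d",
                    i + 1L, length(r) - 1L, dim))
    }
    words[i] <- r[1]
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) abort(sprintf("non-numeric vector at line %d", i + 1L))
    vecs[i, ] <- v
  }
  if (anyDuplicated(words)) {
    inform("duplicate words in embedding file; last occurrence wins")
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  new_embedding_table(words, vecs)
}

#' Write an embedding table in the plain-text word2vec format
#'
#' Only word-level vectors are written; subword n-gram vectors are an
#' in-memory training artefact and are not part of the exchange format.
#'
#' @param table A `dsc_embeddings` table.
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(table$words), table$dim), con)
  body <- vapply(seq_along(table$words), function(i) {
    paste(table$words[i],
          paste(formatC(table$vectors[i, ], format = "g", digits = 17),
                collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(table)
}
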