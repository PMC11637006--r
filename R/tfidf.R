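#' Per-document TF-IDF term weights
#'
#' The weight of word `w` in document `d` is `tf(w, d) * idf(w)` with `tf`
#' the raw within-document count. The default idf is the smoothed variant
#' `ln((1 + N) / (1 + df(w))) + 1`, which keeps corpus-wide words at a
#' positive weight (a zero weight would annihilate their embedding rows in
#' the fused representation); `variant = "raw"` gives the classical
#' `ln(N / df(w))`. Words outside the vocabulary have weight 0. Every
#' occurrence of a word in a document receives the same weight.
#'
#' @param corpus A corpus tibble.
#' @param vocab A vocabulary from [build_vocabulary()].
#' @param variant `"smooth"` (default) or `"raw"` idf.
#' @return A tibble with columns `doc_id`, `word`, `tf`, `idf`, `weight`,
#'   one row per (document, distinct word) pair; attribute `idf` holds the
#'   named per-vocabulary-word idf vector for reuse on new documents.
#' @examples
#' corp <- synth_corpus(K = 2, docs_per_cluster = 3, seed = 1)
#' compute_tfidf(corp, build_vocabulary(corp))
#' @export
compute_tfidf <- function(corpus, vocab, variant = c("smooth", "raw")) {
  variant <- match.arg(variant)
  corpus <- validate_corpus(corpus)
  n_docs <- attr(vocab, "n_docs")
  if (is.null(n_docs)) abort("vocab must come from build_vocabulary()")
  idf <- tfidf_idf(vocab$doc_freq, n_docs, variant)
  names(idf) <- vocab$word

  long <- tidyr::unnest(
    dplyr::select(corpus, "doc_id", "tokens"),
    cols = "tokens"
  )
  counts <- dplyr::count(long, .data$doc_id, word = .data$tokens, name = "tf")
  counts$idf <- unname(idf[counts$word])
  counts$idf[is.na(counts$idf)] <- 0
  counts$weight <- counts$tf * counts$idf
  out <- dplyr::arrange(counts, match(.data$doc_id, corpus$doc_id), .data$word)
  attr(out, "idf") <- idf
  attr(out, "variant") <- variant
  out
}

tfidf_idf <- function(doc_freq, n_docs, variant) {
  switch(variant,
    smooth = log((1 + n_docs) / (1 + doc_freq)) + 1,
    raw = log(n_docs / doc_freq)
  )
}

#' Fuse TF-IDF weights with word embeddings for one document
#'
#' Builds the weighted lexical-semantic feature matrix of a document: row `i`
#' is the embedding of token `i` scaled by that word's TF-IDF weight, giving
#' a `k x dim` matrix (`k` the token count). Rows are exactly zero for words
#' with weight 0 or no known embedding.
#'
#' @param tokens Character vector of the document's tokens (in order).
#' @param table A `dsc_embeddings` table.
#' @param weights Named numeric vector of per-word weights (missing words
#'   get 0), e.g. one document's rows of [compute_tfidf()] as
#'   `setNames(weight, word)`.
#' @return A `k x dim` numeric matrix.
#' @export
fuse <- function(tokens, table, weights) {
  if (length(tokens) == 0) abort("cannot fuse an empty document")
  emb <- embedding_vectors(table, tokens)
  w <- unname(weights[tokens])
  w[is.na(w)] <- 0
  emb * w
}

# Fused matrices for every document of a corpus; ablation switches replace
# the weights with all-ones (no term-frequency feature) and/or the trained
# table with seeded random vectors (no lexical-semantic feature).
fuse_corpus <- function(corpus, table, tfidf) {
  wsplit <- split(setNames(tfidf$weight, tfidf$word), tfidf$doc_id)
  lapply(seq_len(nrow(corpus)), function(i) {
    w <- wsplit[[corpus$doc_id[i]]]
    if (is.null(w)) w <- setNames(numeric(0), character(0))
    fuse(corpus$tokens[[i]], table, w)
  })
}
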