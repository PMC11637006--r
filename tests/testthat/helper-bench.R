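# Shared desk-scale benchmark runner for the synthetic recovery and ablation
# experiments: 3 clusters of 100 short documents, 16-dimensional subword
# embeddings, a 32-unit bidirectional hidden state, 8 epochs of batches of
# 32. Results are cached per (overlap, seed, topic-loss) so several test
# blocks can share runs.

.bench_cache <- new.env(parent = emptyenv())

bench_config <- function(seed, use_topic_loss = TRUE) {
  dsc_config(
    K = 3, batch_size = 32, epochs = 8, hidden_size = 32,
    r_rep = 64, attn_dim = 64, seed = seed,
    use_topic_loss = use_topic_loss
  )
}

run_bench <- function(overlap, seed, use_topic_loss = TRUE) {
  key <- sprintf("ov%s_s%d_t%d", overlap, seed, use_topic_loss)
  if (!is.null(.bench_cache[[key]])) {
    return(.bench_cache[[key]])
  }
  corp <- synth_corpus(K = 3, docs_per_cluster = 100, overlap = overlap,
                       seed = seed)
  vocab <- build_vocabulary(corp)
  tfidf <- compute_tfidf(corp, vocab)
  table <- train_embeddings(corp, dim = 16, subword_n = 2, seed = seed)
  lda <- fit_topic_model(corp, r_topics = 3, seed = seed)
  topics <- document_topic_distribution(lda, corp)
  model <- dsc_train(corp, table, tfidf, topics,
                     bench_config(seed, use_topic_loss))
  base <- baseline_tfidf_kmeans(corp, vocab, K = 3, seed = seed)
  out <- list(
    nmi_full = nmi(corp$label, model$labels),
    nmi_base = nmi(corp$label, base),
    model = NULL, trace = model$trace
  )
  .bench_cache[[key]] <- out
  out
}

# Small corpus + precomputed stages for cheap training-loop tests.
tiny_training_setup <- function(seed = 11, K = 3, docs_per_cluster = 20,
                                overlap = 0.2) {
  corp <- synth_corpus(K = K, docs_per_cluster = docs_per_cluster,
                       vocab_size_per_cluster = 25, shared_vocab_size = 15,
                       doc_len_range = c(4, 12), overlap = overlap,
                       seed = seed)
  vocab <- build_vocabulary(corp)
  tfidf <- compute_tfidf(corp, vocab)
  table <- train_embeddings(corp, dim = 8, seed = seed, epochs = 3)
  lda <- fit_topic_model(corp, r_topics = K, seed = seed, passes = 60)
  topics <- document_topic_distribution(lda, corp)
  list(corpus = corp, vocab = vocab, tfidf = tfidf, table = table,
       topics = topics)
}
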