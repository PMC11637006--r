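test_that("training is bit-reproducible and records a consistent trace", {
  st <- tiny_training_setup()
  cfg <- dsc_config(K = 3, batch_size = 20, epochs = 2, hidden_size = 8,
                    r_rep = 6, attn_dim = 6, seed = 31)
  m1 <- dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg)
  m2 <- dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$labels, m2$labels)

  # joint-loss conservation at every step
  expect_equal(m1$trace$loss_train,
               m1$trace$alpha * m1$trace$loss_cluster + m1$trace$loss_topic,
               tolerance = 1e-9)
  # alpha is non-decreasing, bounded by alpha_max, starts at 0
  expect_equal(m1$trace$alpha[1], 0)
  expect_true(all(diff(m1$trace$alpha) >= 0))
  expect_true(all(m1$trace$alpha <= cfg$alpha_max))
  # learning rate decays linearly
  expect_true(all(diff(m1$trace$lr) < 0))
})

test_that("disabling the cluster loss reduces the joint loss to the topic loss", {
  st <- tiny_training_setup()
  cfg <- dsc_config(K = 3, batch_size = 20, epochs = 2, hidden_size = 8,
                    r_rep = 6, attn_dim = 6, seed = 31,
                    use_cluster_loss = FALSE)
  m <- dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg)
  expect_equal(m$trace$loss_train, m$trace$loss_topic)
  expect_true(all(m$trace$loss_cluster == 0))
})

test_that("training with both losses disabled is a configuration error", {
  st <- tiny_training_setup()
  cfg <- dsc_config(K = 3, batch_size = 20, epochs = 1, hidden_size = 8,
                    use_topic_loss = FALSE, use_cluster_loss = FALSE)
  expect_error(dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg),
               "nothing to optimize")
})

test_that("config invariants are enforced", {
  expect_error(dsc_config(K = 1), "K")
  expect_error(dsc_config(K = 4, batch_size = 3), "batch_size")
  expect_error(dsc_config(alpha_max = 1.4), "alpha_max")
})

test_that("prediction returns one seeded-deterministic label per document", {
  st <- tiny_training_setup()
  cfg <- dsc_config(K = 3, batch_size = 20, epochs = 2, hidden_size = 8,
                    r_rep = 6, attn_dim = 6, seed = 13)
  m <- dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg)
  l1 <- predict_clusters(m, st$corpus, seed = 4)
  l2 <- predict_clusters(m, st$corpus, seed = 4)
  expect_identical(as.integer(l1), as.integer(l2))
  expect_length(l1, nrow(st$corpus))
  expect_true(all(l1 %in% 1:3))
  expect_error(predict_clusters(m, st$corpus[1:2, ]), "smaller than K")
})

test_that("checkpoints round-trip the model exactly", {
  st <- tiny_training_setup()
  cfg <- dsc_config(K = 3, batch_size = 20, epochs = 1, hidden_size = 8,
                    r_rep = 6, attn_dim = 6, seed = 19)
  m <- dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg)
  f <- withr::local_tempfile()
  save_checkpoint(m, f)
  back <- read_checkpoint(f)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
  expect_identical(predict_clusters(back, st$corpus, seed = 1),
                   predict_clusters(m, st$corpus, seed = 1))
})

test_that("the TF-IDF + k-means baseline separates disjoint vocabularies", {
  corp <- synth_corpus(K = 3, docs_per_cluster = 30, shared_vocab_size = 0,
                       overlap = 0, seed = 23)
  labels <- baseline_tfidf_kmeans(corp, K = 3, seed = 1)
  expect_gte(nmi(corp$label, labels), 0.95)
  expect_identical(as.integer(labels),
                   as.integer(baseline_tfidf_kmeans(corp, K = 3, seed = 1)))
  # K = 1 degenerates to a single cluster with zero information
  one <- baseline_tfidf_kmeans(corp, K = 1, seed = 1)
  expect_true(all(one == 1))
  expect_equal(nmi(corp$label, one), 0)
})

test_that("small batches skip the cluster loss with a warning", {
  st <- tiny_training_setup()
  # 60 documents in batches of 32: the final batch of 28 still exceeds K,
  # so force a tiny trailing batch instead
  cfg <- dsc_config(K = 3, batch_size = 58, epochs = 1, hidden_size = 8,
                    r_rep = 6, attn_dim = 6, seed = 3,
                    use_topic_loss = TRUE)
  expect_warning(
    m <- dsc_train(st$corpus, st$table, st$tfidf, st$topics, cfg),
    "cluster loss skipped"
  )
  expect_equal(m$trace$loss_cluster[2], 0)
})
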