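test_that("boundary-marked n-grams follow the definition", {
  expect_equal(subword_ngrams("ab", 2), c("<a", "ab", "b>"))
  expect_equal(subword_ngrams("x", 2), c("<x", "x>"))
  # a 3-unit token yields 4 bigram pieces
  expect_length(subword_ngrams("abc", 2), 4)
  expect_equal(subword_ngrams("abc", 10), "<abc>")
  expect_error(subword_ngrams("", 2), "non-empty")
})

test_that("training is seeded-deterministic with correct shapes", {
  corp <- synth_corpus(K = 2, docs_per_cluster = 100,
                       vocab_size_per_cluster = 25, seed = 8)
  a <- train_embeddings(corp, dim = 16, seed = 1703, epochs = 3)
  b <- train_embeddings(corp, dim = 16, seed = 1703, epochs = 3)
  expect_identical(a$vectors, b$vectors)
  expect_equal(ncol(a$vectors), 16)
  expect_equal(sort(a$words), sort(build_vocabulary(corp)$word))
})

test_that("words with identical context distributions embed closer than typical pairs", {
  # each document carries exactly one of two interchangeable marker words,
  # so the two markers share a context distribution
  filler <- sprintf("f%d", 1:30)
  set.seed(42)
  docs <- replicate(150, {
    k <- sample(4:8, 1)
    toks <- sample(filler, k, replace = TRUE)
    toks[sample(k, 1)] <- sample(c("mkA", "mkB"), 1)
    toks
  }, simplify = FALSE)
  corp <- tibble::tibble(doc_id = sprintf("d%d", seq_along(docs)),
                         tokens = docs, label = NA_integer_)
  tab <- train_embeddings(corp, dim = 16, seed = 3, epochs = 8)
  V <- tab$vectors / sqrt(rowSums(tab$vectors^2))
  cos <- V %*% t(V)
  pair <- cos["mkA", "mkB"]
  off <- cos[upper.tri(cos)]
  expect_gt(pair, stats::median(off))
})

test_that("subword composition embeds unseen words from known n-grams", {
  corp <- synth_corpus(K = 2, docs_per_cluster = 20, seed = 5)
  tab <- train_embeddings(corp, dim = 8, subword_n = 2, seed = 2,
                          method = "random")
  # unseen word sharing n-grams with vocabulary words gets a nonzero vector
  w <- tab$words[1]
  expect_false(all(embedding_vectors(tab, w) == 0))
  novel <- paste0(substr(w, 1, nchar(w) - 1), "#")
  vnovel <- embedding_vectors(tab, novel)[1, ]
  hit <- intersect(subword_ngrams(novel, 2), rownames(tab$ngram_vectors))
  expect_equal(vnovel, colSums(tab$ngram_vectors[hit, , drop = FALSE]),
               ignore_attr = TRUE)
  # word with no known pieces is the zero vector
  expect_true(all(embedding_vectors(tab, "ZZZZZZ") == 0))
})

test_that("word2vec text format round-trips and validates", {
  f <- withr::local_tempfile(lines = c("2 3", "a 1 0 0", "b 0 1 0"))
  tab <- read_embeddings(f)
  expect_equal(tab$dim, 3)
  expect_equal(tab$words, c("a", "b"))
  expect_equal(unname(tab$vectors["a", ]), c(1, 0, 0))

  bad <- withr::local_tempfile(lines = c("2 3", "a 1 0 0", "b 0 1"))
  expect_error(read_embeddings(bad), "line 3")

  dup <- withr::local_tempfile(lines = c("2 2", "a 1 0", "a 0 2"))
  expect_message(tabd <- read_embeddings(dup), "last occurrence")
  expect_equal(unname(tabd$vectors["a", ]), c(0, 2))

  corp <- synth_corpus(K = 2, docs_per_cluster = 10, seed = 6)
  trained <- train_embeddings(corp, dim = 5, seed = 1, epochs = 2)
  out <- withr::local_tempfile()
  write_embeddings(trained, out)
  back <- read_embeddings(out)
  expect_equal(back$words, trained$words)
  expect_equal(back$vectors, trained$vectors, tolerance = 1e-12)
})
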