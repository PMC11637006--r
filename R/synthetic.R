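#' Generate a labelled synthetic short-text corpus
#'
#' Emulates the short-document regime the clustering pipeline targets: `K`
#' topic-clusters, each with its own private vocabulary under a Zipf-shaped
#' word distribution, plus a shared vocabulary pool. Each token of a document
#' in cluster `c` is drawn from the shared pool with probability `overlap`
#' and from cluster `c`'s private pool otherwise, so `overlap = 0` (with
#' `shared_vocab_size = 0`) gives pairwise-disjoint cluster vocabularies and
#' `overlap = 1` makes all clusters share one word distribution.
#'
#' @param K Number of clusters (>= 2 for anything interesting).
#' @param docs_per_cluster Documents generated per cluster.
#' @param vocab_size_per_cluster Size of each cluster's private vocabulary.
#' @param shared_vocab_size Size of the shared pool (must be > 0 if
#'   `overlap > 0`).
#' @param doc_len_range Inclusive `(min, max)` token count per document.
#' @param overlap Probability, in `[0, 1]`, that a token comes from the
#'   shared pool.
#' @param zipf_exponent Zipf exponent of the within-pool rank-frequency law;
#'   1.1 mimics natural-language skew (a uniform law would make idf useless).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A corpus tibble (see [read_corpus()]) with `label` in `1..K`.
#' @examples
#' synth_corpus(K = 3, docs_per_cluster = 5, seed = 1)
#' @export
synth_corpus <- function(K, docs_per_cluster,
                         vocab_size_per_cluster = 50L,
                         shared_vocab_size = 30L,
                         doc_len_range = c(5L, 30L),
                         overlap = 0,
                         zipf_exponent = 1.1,
                         seed = 1L) {
  if (K < 1 || docs_per_cluster < 1) abort("K and docs_per_cluster must be >= 1")
  if (overlap < 0 || overlap > 1) abort("overlap must lie in [0, 1]")
  if (overlap > 0 && shared_vocab_size < 1) {
    abort("overlap > 0 requires a non-empty shared pool")
  }
  if (doc_len_range[1] < 1 || doc_len_range[2] < doc_len_range[1]) {
    abort("doc_len_range must satisfy 1 <= min <= max")
  }
  zipf <- function(v) {
    p <- seq_len(v)^(-zipf_exponent)
    p / sum(p)
  }
  cluster_words <- lapply(seq_len(K), function(k) {
    sprintf("c%d_w%d", k, seq_len(vocab_size_per_cluster))
  })
  shared_words <- if (shared_vocab_size > 0) {
    sprintf("sh_w%d", seq_len(shared_vocab_size))
  } else {
    character()
  }
  p_private <- zipf(vocab_size_per_cluster)
  p_shared <- if (shared_vocab_size > 0) zipf(shared_vocab_size) else numeric()

  with_seed(stage_seed(seed, "synth"), {
    n <- K * docs_per_cluster
    labels <- rep(seq_len(K), each = docs_per_cluster)
    lens <- sample(seq(doc_len_range[1], doc_len_range[2]), n, replace = TRUE)
    toks <- lapply(seq_len(n), function(i) {
      k <- labels[i]
      from_shared <- runif(lens[i]) < overlap
      out <- character(lens[i])
      n_sh <- sum(from_shared)
      if (n_sh > 0) {
        out[from_shared] <- sample(shared_words, n_sh, replace = TRUE,
                                   prob = p_shared)
      }
      if (n_sh < lens[i]) {
        out[!from_shared] <- sample(cluster_words[[k]], lens[i] - n_sh,
                                    replace = TRUE, prob = p_private)
      }
      out
    })
    tibble(
      doc_id = sprintf("doc%d", seq_len(n)),
      tokens = toks,
      label = as.integer(labels)
    )
  })
}

#' Generate corpora along a difficulty sweep
#'
#' One corpus per overlap value, with seeds derived as `seed + index - 1` so
#' the sweep is reproducible and each point re-creatable in isolation.
#'
#' @param overlaps Ascending vector of overlap values in `[0, 1]`.
#' @param ... Passed to [synth_corpus()] (everything but `overlap`/`seed`).
#' @param seed Base seed.
#' @return A tibble with columns `overlap`, `seed` and list-column `corpus`.
#' @export
difficulty_sweep <- function(overlaps, ..., seed = 1L) {
  if (is.unsorted(overlaps)) abort("overlaps must be sorted ascending")
  tibble(
    overlap = overlaps,
    seed = seed + seq_along(overlaps) - 1L,
    corpus = purrr::map2(overlaps, seed + seq_along(overlaps) - 1L,
                         function(ov, s) synth_corpus(..., overlap = ov,
                                                      seed = s))
  )
}
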