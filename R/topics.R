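#' Fit the cross-document LDA topic model
#'
#' Fits smoothed latent Dirichlet allocation by collapsed Gibbs sampling on
#' the corpus bag-of-words. The resulting document-topic distribution is the
#' frozen self-supervised target of the topic loss: it is computed once,
#' before encoder training, and never co-trained. The number of topics
#' defaults to the number of clusters downstream, reflecting the assumed
#' one-to-one correspondence between document clusters and topics.
#'
#' @param corpus A corpus tibble.
#' @param r_topics Number of topics (>= 2).
#' @param seed Integer seed (sampler is deterministic given it).
#' @param passes Gibbs passes; the second half is averaged for the
#'   document-topic posterior.
#' @param alpha Symmetric document-topic Dirichlet prior
#'   (default `1 / r_topics`).
#' @param eta Symmetric topic-word Dirichlet prior (default `1 / r_topics`).
#' @return A `dsc_lda` model with the topic-word matrix `phi`
#'   (`r_topics x vocab`), the training-corpus posterior `theta`, and the
#'   vocabulary it indexes.
#' @export
fit_topic_model <- function(corpus, r_topics, seed = 1L, passes = 200L,
                            alpha = NULL, eta = NULL) {
  corpus <- validate_corpus(corpus)
  if (r_topics < 2) abort("r_topics must be >= 2")
  vocab <- build_vocabulary(corpus)
  if (r_topics > nrow(vocab)) {
    abort(sprintf("r_topics (%d) exceeds vocabulary size (%d)",
                  r_topics, nrow(vocab)))
  }
  alpha <- alpha %||% (1 / r_topics)
  eta <- eta %||% (1 / r_topics)
  docs <- lapply(corpus$tokens, function(tk) {
    idx <- match(tk, vocab$word)
    as.integer(idx[!is.na(idx)] - 1L)
  })
  fit <- lda_gibbs_cpp(docs, nrow(vocab), as.integer(r_topics),
                       alpha, eta, as.integer(passes),
                       as.integer(passes %/% 2L),
                       as.integer(stage_seed(seed, "lda")))
  phi <- fit$topic_word + eta
  phi <- phi / rowSums(phi)
  colnames(phi) <- vocab$word
  theta <- fit$theta
  # documents whose every token is out-of-vocabulary carry no evidence
  oov <- lengths(docs) == 0
  theta[oov, ] <- 1 / r_topics
  structure(
    list(phi = phi, theta = theta, vocab = vocab, r_topics = r_topics,
         alpha = alpha, eta = eta, doc_ids = corpus$doc_id),
    class = "dsc_lda"
  )
}

#' @export
print.dsc_lda <- function(x, ...) {
  cat(sprintf("<dsc_lda: %d topics over %d words, %d documents>\n",
              x$r_topics, ncol(x$phi), nrow(x$theta)))
  invisible(x)
}

#' Document-topic distributions under a fitted topic model
#'
#' Infers one probability vector over topics per document by deterministic
#' fold-in: iterated expectation of the token-topic responsibilities under
#' the frozen topic-word matrix, starting from the uniform distribution.
#' Every entry is strictly positive (Dirichlet smoothing), so downstream
#' KL divergences are finite; an all-out-of-vocabulary document gets the
#' uniform distribution.
#'
#' @param model A `dsc_lda` model.
#' @param corpus A corpus tibble (any corpus over a compatible vocabulary).
#' @param iterations Fold-in fixed-point iterations.
#' @return A `n_docs x r_topics` matrix; rows sum to 1.
#' @export
document_topic_distribution <- function(model, corpus, iterations = 50L) {
  corpus <- validate_corpus(corpus)
  K <- model$r_topics
  out <- matrix(1 / K, nrow(corpus), K)
  for (i in seq_len(nrow(corpus))) {
    idx <- match(corpus$tokens[[i]], colnames(model$phi))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) next
    pw <- model$phi[, idx, drop = FALSE] # K x k
    theta <- rep(1 / K, K)
    for (it in seq_len(iterations)) {
      resp <- pw * theta # K x k
      resp <- sweep(resp, 2, colSums(resp), "/")
      theta_new <- (rowSums(resp) + model$alpha) /
        (length(idx) + K * model$alpha)
      if (max(abs(theta_new - theta)) < 1e-10) {
        theta <- theta_new
        break
      }
      theta <- theta_new
    }
    out[i, ] <- theta
  }
  rownames(out) <- corpus$doc_id
  out
}
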