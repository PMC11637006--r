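#' Training configuration
#'
#' Bundles every tunable of the double-target training loop. Defaults follow
#' the reference setting for a 12-category short-text corpus: 12 clusters,
#' AdamW at learning rate 1e-3 with linear decay, 32 epochs, batch size 256,
#' bidirectional hidden size 512, representation length 64, cluster-loss
#' weight climbing to 0.3 over the run. The four ablation switches disable,
#' respectively, the TF-IDF weighting (weights become all-ones), the trained
#' word embeddings (replaced by seeded random vectors), the topic KL loss
#' and the batch cluster loss.
#'
#' @param K Number of clusters (>= 2).
#' @param r_topics Number of LDA topics; defaults to `K` under the assumed
#'   one-to-one cluster/topic correspondence.
#' @param batch_size Mini-batch size (>= K so a batch can hold K centroids).
#' @param epochs Training epochs.
#' @param learning_rate Initial learning rate.
#' @param lr_linear_decay Linearly decay the learning rate to 0 over the run.
#' @param alpha_max Final cluster-loss weight, in `[0, 1]`.
#' @param T_ramp Ramp length of the climbing schedule, in epochs; defaults
#'   to `epochs`.
#' @param seed Master seed; per-stage seeds derive from it.
#' @param optimizer `"adamw"` (default) or `"sgd"`.
#' @param weight_decay AdamW decoupled weight decay.
#' @param cluster_variant `"assigned"` or `"all_centroids"`, see
#'   [cluster_loss()].
#' @param reduction `"sum"` (default) or `"mean"` over the batch; both
#'   losses always share the same reduction so their balance is unchanged.
#' @param use_tfidf,use_embeddings,use_topic_loss,use_cluster_loss Ablation
#'   switches.
#' @param hidden_size,r_rep,attn_dim,hops,init,init_sd Encoder architecture
#'   and initialization, see [encoder_params()].
#' @return A `dsc_config` list.
#' @export
dsc_config <- function(K = 12L, r_topics = K, batch_size = 256L,
                       epochs = 32L, learning_rate = 1e-3,
                       lr_linear_decay = TRUE, alpha_max = 0.3,
                       T_ramp = epochs, seed = 1L,
                       optimizer = c("adamw", "sgd"), weight_decay = 0.01,
                       cluster_variant = c("assigned", "all_centroids"),
                       reduction = c("sum", "mean"),
                       use_tfidf = TRUE, use_embeddings = TRUE,
                       use_topic_loss = TRUE, use_cluster_loss = TRUE,
                       hidden_size = 512L, r_rep = 64L, attn_dim = 64L,
                       hops = 1L, init = c("scaled", "constant"),
                       init_sd = 0.02) {
  if (K < 2) abort("K must be >= 2")
  if (alpha_max < 0 || alpha_max > 1) abort("alpha_max must lie in [0, 1]")
  if (batch_size < K) abort("batch_size must be >= K")
  if (T_ramp < 1) abort("T_ramp must be >= 1")
  structure(
    list(K = as.integer(K), r_topics = as.integer(r_topics),
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = learning_rate, lr_linear_decay = lr_linear_decay,
         alpha_max = alpha_max, T_ramp = as.integer(T_ramp),
         seed = as.integer(seed), optimizer = match.arg(optimizer),
         weight_decay = weight_decay,
         cluster_variant = match.arg(cluster_variant),
         reduction = match.arg(reduction),
         use_tfidf = use_tfidf, use_embeddings = use_embeddings,
         use_topic_loss = use_topic_loss, use_cluster_loss = use_cluster_loss,
         hidden_size = as.integer(hidden_size), r_rep = as.integer(r_rep),
         attn_dim = as.integer(attn_dim), hops = as.integer(hops),
         init = match.arg(init), init_sd = init_sd),
    class = "dsc_config"
  )
}

adamw_step <- function(params, grads, state, lr, optimizer, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (optimizer == "sgd") {
    for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    return(list(params = params, state = state))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' Train the double-target self-supervised clustering model
#'
#' Runs the end-to-end training loop: per epoch the documents are shuffled
#' (seeded) and processed in mini-batches; each batch's fused token matrices
#' are encoded to text representations `M`; when the cluster loss is on, a
#' fresh within-batch k-means (detached from the gradient) provides the
#' centroids of the attraction loss; when the topic loss is on, the model's
#' topic posterior is pulled toward the frozen LDA document-topic rows by KL
#' divergence. The joint loss `alpha * L_cluster + L_topic` (with `alpha`
#' climbing per [alpha_schedule()]) is minimized by AdamW under linear
#' learning-rate decay. After training, the whole corpus is encoded and
#' clustered once to give final labels and global centroids.
#'
#' @param corpus A corpus tibble.
#' @param embeddings A `dsc_embeddings` table covering the corpus.
#' @param tfidf Output of [compute_tfidf()] on (a superset of) the corpus.
#' @param topics `n_docs x r_topics` matrix of frozen document-topic rows,
#'   aligned with `corpus` (see [document_topic_distribution()]).
#' @param config A [dsc_config()].
#' @return A `dsc_model` with the trained encoder parameters, the embedded
#'   config, the frozen topic targets, final global centroids and labels,
#'   and the per-step loss trace (columns `epoch`, `step`, `alpha`, `lr`,
#'   `n`, `loss_cluster`, `loss_topic`, `loss_train`).
#' @export
dsc_train <- function(corpus, embeddings, tfidf, topics, config) {
  corpus <- validate_corpus(corpus)
  if (!config$use_topic_loss && !config$use_cluster_loss) {
    abort("configuration error: both losses disabled, nothing to optimize")
  }
  n <- nrow(corpus)
  topics <- as.matrix(topics)
  if (nrow(topics) != n || ncol(topics) != config$r_topics) {
    abort("topics matrix does not match corpus / r_topics")
  }
  if (!config$use_embeddings) {
    embeddings <- randomized_table(embeddings, config$seed)
  }
  if (!config$use_tfidf) {
    tfidf$weight <- rep(1, nrow(tfidf))
  }
  fws <- fuse_corpus(corpus, embeddings, tfidf)

  train_seed <- stage_seed(config$seed, "train")
  params <- encoder_params(
    emb_dim = embeddings$dim, r_topics = config$r_topics,
    hidden_size = config$hidden_size, r_rep = config$r_rep,
    attn_dim = config$attn_dim, hops = config$hops,
    init = config$init, init_sd = config$init_sd, seed = train_seed
  )
  wn <- weight_names()
  state <- list(t = 0L,
                m = lapply(params[wn], function(w) w * 0),
                v = lapply(params[wn], function(w) w * 0))

  n_batches <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * n_batches
  trace <- vector("list", total_steps)
  step <- 0L
  small_batch_warned <- FALSE

  for (epoch in seq_len(config$epochs)) {
    alpha <- alpha_schedule(epoch - 1L, config$T_ramp, config$alpha_max)
    order <- with_seed(train_seed + epoch, sample.int(n))
    for (b in seq_len(n_batches)) {
      step <- step + 1L
      lr <- if (config$lr_linear_decay) {
        config$learning_rate * (1 - (step - 1) / total_steps)
      } else {
        config$learning_rate
      }
      idx <- order[((b - 1L) * config$batch_size + 1L):
                     min(b * config$batch_size, n)]
      m <- length(idx)
      fwd <- encoder_forward(fws[idx], params)
      M <- fwd$M
      red <- if (config$reduction == "mean") m else 1

      lc <- 0
      dM <- matrix(0, m, config$r_rep)
      if (config$use_cluster_loss) {
        if (m >= config$K) {
          bc <- batch_kmeans(M, config$K, seed = train_seed + 997L + step)
          lc <- cluster_loss(M, bc, config$cluster_variant) / red
          dM <- alpha * cluster_loss_grad(M, bc, config$cluster_variant) / red
        } else if (!small_batch_warned) {
          warn(sprintf(
            "batch of %d samples < K = %d: cluster loss skipped for it",
            m, config$K))
          small_batch_warned <- TRUE
        }
      }
      head_out <- head_forward(M, params)
      lt <- 0
      dlogits <- matrix(0, m, config$r_topics)
      if (config$use_topic_loss) {
        Tb <- topics[idx, , drop = FALSE]
        lt <- topic_loss(Tb, head_out$D) / red
        dlogits <- (head_out$D - Tb) / red
      }
      ltrain <- joint_loss(lc, lt, alpha)
      grads <- encoder_backward(params, fwd, head_out, dM, dlogits)
      stepped <- adamw_step(params[wn], grads, state, lr,
                            config$optimizer, config$weight_decay)
      params[wn] <- stepped$params
      state <- stepped$state
      trace[[step]] <- tibble(
        epoch = epoch, step = step, alpha = alpha, lr = lr, n = m,
        loss_cluster = lc, loss_topic = lt, loss_train = ltrain
      )
    }
  }
  trace <- dplyr::bind_rows(trace)

  model <- structure(
    list(params = params, config = config, embeddings = embeddings,
         idf = attr(tfidf, "idf"), topics = topics, trace = trace,
         version = 1L),
    class = "dsc_model"
  )
  final <- predict_clusters(model, corpus, K = config$K,
                            seed = stage_seed(config$seed, "predict"))
  model$centroids <- attr(final, "centroids")
  model$labels <- as.integer(final)
  model
}

# Same words/dim as `table` but seeded random normal vectors: the
# "no lexical-semantic features" ablation.
randomized_table <- function(table, seed) {
  vecs <- with_seed(stage_seed(seed, "embeddings") + 1L, {
    matrix(rnorm(length(table$words) * table$dim, sd = 1 / sqrt(table$dim)),
           length(table$words), table$dim)
  })
  new_embedding_table(table$words, vecs)
}

# TF-IDF weights for a (possibly new) corpus under a frozen idf vector.
corpus_weights <- function(corpus, idf) {
  long <- tidyr::unnest(dplyr::select(corpus, "doc_id", "tokens"),
                        cols = "tokens")
  counts <- dplyr::count(long, .data$doc_id, word = .data$tokens, name = "tf")
  counts$idf <- unname(idf[counts$word])
  counts$idf[is.na(counts$idf)] <- 0
  counts$weight <- counts$tf * counts$idf
  attr(counts, "idf") <- idf
  counts
}

#' Cluster a corpus with a trained model
#'
#' Encodes every document into the learned representation space and runs
#' k-means (10 seeded k-means++ restarts, best inertia kept) over the full
#' corpus.
#'
#' @param model A trained `dsc_model`.
#' @param corpus A corpus tibble (tokens only are used).
#' @param K Number of clusters; defaults to the training K.
#' @param seed Integer seed.
#' @param restarts k-means restarts.
#' @return Integer label vector in `1..K`, one per document, with the
#'   `K x r_rep` centroid matrix as attribute `centroids`.
#' @export
predict_clusters <- function(model, corpus, K = model$config$K, seed = 1L,
                             restarts = 10L) {
  corpus <- validate_corpus(corpus)
  if (nrow(corpus) < K) abort("corpus smaller than K")
  tfidf <- corpus_weights(corpus, model$idf)
  if (!model$config$use_tfidf) tfidf$weight <- rep(1, nrow(tfidf))
  fws <- fuse_corpus(corpus, model$embeddings, tfidf)
  M <- encode_corpus(fws, model$params, model$config$batch_size)
  fit <- batch_kmeans(M, K, seed = seed, restarts = restarts)
  structure(fit$assign, centroids = fit$centroids, names = corpus$doc_id)
}

#' @export
predict.dsc_model <- function(object, newdata, ...) {
  predict_clusters(object, newdata, ...)
}

#' TF-IDF + k-means baseline
#'
#' The classical vector-space baseline: each document becomes a TF-IDF
#' bag-of-words vector over the vocabulary (same idf variant as
#' [compute_tfidf()]), clustered by k-means with seeded k-means++ restarts.
#'
#' @param corpus A corpus tibble.
#' @param vocab A vocabulary from [build_vocabulary()]; defaults to one
#'   built from `corpus`.
#' @param K Number of clusters.
#' @param seed Integer seed.
#' @param restarts k-means restarts.
#' @param variant idf variant, see [compute_tfidf()].
#' @return Integer label vector in `1..K` with attribute `centroids`.
#' @export
baseline_tfidf_kmeans <- function(corpus, vocab = NULL, K, seed = 1L,
                                  restarts = 10L,
                                  variant = c("smooth", "raw")) {
  variant <- match.arg(variant)
  corpus <- validate_corpus(corpus)
  if (nrow(corpus) < K) abort("corpus smaller than K")
  vocab <- vocab %||% build_vocabulary(corpus)
  tfidf <- compute_tfidf(corpus, vocab, variant)
  X <- matrix(0, nrow(corpus), nrow(vocab),
              dimnames = list(corpus$doc_id, vocab$word))
  wi <- match(tfidf$word, vocab$word)
  di <- match(tfidf$doc_id, corpus$doc_id)
  keep <- !is.na(wi)
  X[cbind(di[keep], wi[keep])] <- tfidf$weight[keep]
  fit <- batch_kmeans(X, K, seed = stage_seed(seed, "baseline"),
                      restarts = restarts)
  structure(fit$assign, centroids = fit$centroids, names = corpus$doc_id)
}

#' Serialize / restore a trained model
#'
#' The checkpoint is a single file embedding a format version and the full
#' config; reading it back restores the model bit-exactly.
#'
#' @param model A `dsc_model`.
#' @param path Checkpoint path.
#' @return `save_checkpoint`: `path`, invisibly. `read_checkpoint`: the
#'   restored `dsc_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dsc_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dsc_model")) abort("not a dsclust checkpoint")
  model
}
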