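#' Climbing schedule for the cluster-loss weight
#'
#' The cluster-loss weight ramps linearly from 0 to `alpha_max` over
#' `T_ramp` epochs — `alpha(t) = (t / T_ramp) * alpha_max` for
#' `t <= T_ramp` — and stays clamped at `alpha_max` afterwards. Early in
#' training the encoded features are still poor, and a full-strength
#' centroid-attraction loss on them would be counterproductive.
#'
#' @param t Epoch index, 0-based (>= 0).
#' @param T_ramp Ramp length in epochs (>= 1).
#' @param alpha_max Final weight, in `[0, 1]`; default 0.3.
#' @return The weight at epoch `t`.
#' @examples
#' alpha_schedule(0, 32)   # 0
#' alpha_schedule(32, 32)  # 0.3
#' alpha_schedule(64, 32)  # clamped at 0.3
#' @export
alpha_schedule <- function(t, T_ramp, alpha_max = 0.3) {
  if (T_ramp < 1) abort("T_ramp must be >= 1")
  if (any(t < 0)) abort("epoch index must be >= 0")
  pmin(t / T_ramp, 1) * alpha_max
}

# k-means++ initial centroids, drawn with the supplied RNG state.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (k in seq_len(K)[-1]) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k, ] <- x[sample.int(n, 1, prob = p), ]
    dk <- rowSums((x - matrix(centers[k, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dk)
  }
  centers
}

nearest_centroid <- function(x, centers) {
  # squared distances via ||x||^2 - 2 x.c + ||c||^2
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) - 2 * cross +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  list(assign = max.col(-d2, ties.method = "first"),
       dist2 = d2[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))])
}

# Lloyd iterations from given centers; empty clusters keep their centroid.
lloyd <- function(x, centers, max_iter = 100L) {
  K <- nrow(centers)
  assign_prev <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    nc <- nearest_centroid(x, centers)
    if (identical(nc$assign, assign_prev)) break
    assign_prev <- nc$assign
    for (k in seq_len(K)) {
      rows <- nc$assign == k
      if (any(rows)) centers[k, ] <- colMeans(x[rows, , drop = FALSE])
    }
  }
  nc <- nearest_centroid(x, centers)
  list(centers = centers, assign = nc$assign, inertia = sum(nc$dist2),
       iterations = it)
}

#' Within-batch k-means clustering
#'
#' Lloyd's algorithm with seeded k-means++ initialization, run on the
#' encoded features of one mini-batch (at most 100 iterations). Each sample
#' ends assigned to its nearest centroid under squared Euclidean distance.
#'
#' @param features `m x r` numeric matrix of batch features.
#' @param K Number of centroids (`m >= K` required).
#' @param seed Integer seed for the initialization.
#' @param restarts Number of k-means++ restarts; the lowest-inertia solution
#'   wins.
#' @return List with `centroids` (`K x r`), `assign` (length `m`, in
#'   `1..K`) and `inertia`.
#' @export
batch_kmeans <- function(features, K, seed = 1L, restarts = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < K) {
    abort(sprintf("batch of %d samples cannot support %d centroids",
                  nrow(features), K))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- lloyd(features, kmeanspp_init(features, K))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    list(centroids = best$centers, assign = best$assign,
         inertia = best$inertia)
  })
}

#' Batch clustering loss
#'
#' Sum over batch samples of the squared Euclidean distance between each
#' feature vector and a centroid. The default `"assigned"` variant measures
#' distance to the sample's own (nearest) centroid — the reading under which
#' the loss pulls features toward the centroid structure found by k-means.
#' The `"all_centroids"` variant sums the distance to every centroid for
#' every sample, the literal double-sum; it is provided for comparison.
#' Centroids are constants: gradients flow to the features only.
#'
#' @param features `m x r` feature matrix.
#' @param clustering A [batch_kmeans()] result (or any list with `centroids`
#'   and `assign`).
#' @param variant `"assigned"` (default) or `"all_centroids"`.
#' @return Non-negative scalar loss.
#' @export
cluster_loss <- function(features, clustering,
                         variant = c("assigned", "all_centroids")) {
  variant <- match.arg(variant)
  features <- as.matrix(features)
  if (variant == "assigned") {
    if (length(clustering$assign) != nrow(features)) {
      abort("assignment does not cover the batch")
    }
    diff <- features - clustering$centroids[clustering$assign, , drop = FALSE]
    sum(diff^2)
  } else {
    sum(vapply(seq_len(nrow(clustering$centroids)), function(k) {
      sum((features - matrix(clustering$centroids[k, ], nrow(features),
                             ncol(features), byrow = TRUE))^2)
    }, 0))
  }
}

# Gradient of cluster_loss w.r.t. features (m x r).
cluster_loss_grad <- function(features, clustering,
                              variant = c("assigned", "all_centroids")) {
  variant <- match.arg(variant)
  features <- as.matrix(features)
  if (variant == "assigned") {
    2 * (features - clustering$centroids[clustering$assign, , drop = FALSE])
  } else {
    K <- nrow(clustering$centroids)
    2 * (K * features -
           matrix(colSums(clustering$centroids), nrow(features),
                  ncol(features), byrow = TRUE))
  }
}

#' Topic target loss (KL divergence)
#'
#' `sum_i sum_j t_ij * ln(t_ij / d_ij)`: the Kullback-Leibler divergence
#' from the frozen LDA document-topic rows `T` to the model's topic
#' posterior rows `D`, summed over the batch. Zero target entries contribute
#' zero; posterior entries are floored at `1e-12` so the loss is always
#' finite.
#'
#' @param T_batch `m x r_topics` matrix of target simplex rows.
#' @param D_batch `m x r_topics` matrix of posterior simplex rows.
#' @return Non-negative scalar.
#' @export
topic_loss <- function(T_batch, D_batch) {
  T_batch <- as.matrix(T_batch)
  D_batch <- as.matrix(D_batch)
  if (!all(dim(T_batch) == dim(D_batch))) {
    abort("topic_loss: T and D dimensions differ")
  }
  d <- pmax(D_batch, 1e-12)
  terms <- ifelse(T_batch > 0, T_batch * log(T_batch / d), 0)
  sum(terms)
}

#' Joint training loss
#'
#' `alpha * L_cluster + L_topic`: the double self-supervised objective, a
#' climbing-weighted centroid attraction plus the topic KL term.
#'
#' @param lc Cluster loss value.
#' @param lt Topic loss value.
#' @param alpha Cluster-loss weight (>= 0).
#' @return The combined loss.
#' @export
joint_loss <- function(lc, lt, alpha) {
  if (alpha < 0) abort("alpha must be >= 0")
  alpha * lc + lt
}
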