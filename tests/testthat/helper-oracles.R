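# Independent from-the-definition oracles used to validate the package's
# metric and loss implementations. These deliberately use naive enumeration
# and direct formulas, not the package's code paths.

# Best accuracy over all injective mappings of predicted clusters to gold
# classes, by exhaustive enumeration (feasible for <= 6 clusters).
brute_force_acc <- function(gold, pred) {
  tab <- table(pred, gold)
  np <- nrow(tab)
  ng <- ncol(tab)
  n <- max(np, ng)
  padded <- matrix(0, n, n)
  padded[seq_len(np), seq_len(ng)] <- tab
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(n))) {
    best <- max(best, sum(padded[cbind(seq_len(n), p)]))
  }
  best / length(gold)
}

nmi_oracle <- function(gold, pred) {
  tab <- as.matrix(table(pred, gold))
  n <- sum(tab)
  H <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
  }
  hg <- H(colSums(tab))
  hp <- H(rowSums(tab))
  if (hg == 0 && hp == 0) return(1)
  if (hg == 0 || hp == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0) {
      mi <- mi + (nij / n) * log((nij / n) / ((sum(tab[i, ]) / n) *
                                                (sum(tab[, j]) / n)))
    }
  }
  mi / mean(c(hg, hp))
}

ari_oracle <- function(gold, pred) {
  n <- length(gold)
  # direct pair enumeration
  a <- 0; b <- 0; c_ <- 0; d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sg <- gold[i] == gold[j]
    sp <- pred[i] == pred[j]
    if (sg && sp) a <- a + 1
    else if (!sg && sp) b <- b + 1
    else if (sg && !sp) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  expected <- (a + c_) * (a + b) / tot
  maxi <- ((a + c_) + (a + b)) / 2
  if (maxi == expected) return(ifelse(a == maxi, 1, 0))
  (a - expected) / (maxi - expected)
}

pairwise_f1_oracle <- function(gold, pred) {
  n <- length(gold)
  tp <- 0; pred_pos <- 0; gold_pos <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- pred[i] == pred[j]
    sg <- gold[i] == gold[j]
    if (sp) pred_pos <- pred_pos + 1
    if (sg) gold_pos <- gold_pos + 1
    if (sp && sg) tp <- tp + 1
  }
  if (pred_pos == 0 && gold_pos == 0) return(1)
  if (pred_pos == 0 || gold_pos == 0) return(0)
  prec <- tp / pred_pos
  rec <- tp / gold_pos
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Scalar step-by-step GRU cell evaluation (reset/update gates, candidate,
# convex state update), kept deliberately element-wise.
gru_step_oracle <- function(x, h, Wr, Wz, Wh) {
  sig <- function(v) 1 / (1 + exp(-v))
  u <- length(h)
  r <- numeric(u); z <- numeric(u); ht <- numeric(u); out <- numeric(u)
  hx <- c(h, x)
  for (i in seq_len(u)) {
    r[i] <- sig(sum(Wr[i, ] * hx))
    z[i] <- sig(sum(Wz[i, ] * hx))
  }
  rhx <- c(r * h, x)
  for (i in seq_len(u)) ht[i] <- tanh(sum(Wh[i, ] * rhx))
  for (i in seq_len(u)) out[i] <- (1 - z[i]) * h[i] + z[i] * ht[i]
  out
}

# Scalar evaluation of the attention + projection stack for one document.
self_attend_oracle <- function(H, W1a, W2a, P1, P2) {
  k <- nrow(H)
  hops <- nrow(W2a)
  G <- matrix(0, nrow(W1a), k)
  for (a in seq_len(nrow(W1a))) for (t in seq_len(k)) {
    G[a, t] <- tanh(sum(W1a[a, ] * H[t, ]))
  }
  Z <- matrix(0, hops, k)
  for (r in seq_len(hops)) for (t in seq_len(k)) {
    Z[r, t] <- sum(W2a[r, ] * G[, t])
  }
  A <- matrix(0, hops, k)
  for (r in seq_len(hops)) A[r, ] <- exp(Z[r, ]) / sum(exp(Z[r, ]))
  zhat <- A %*% H
  zvec <- as.vector(t(zhat))
  s <- numeric(ncol(P1))
  for (p in seq_len(ncol(P1))) s[p] <- tanh(sum(P1[, p] * zvec))
  M <- numeric(nrow(P2))
  for (o in seq_len(nrow(P2))) M[o] <- sum(P2[o, ] * s)
  list(A = A, M = M)
}

random_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}
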