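#' Initialize encoder parameters
#'
#' All weight blocks are drawn from a random normal distribution
#' (`sd = init_sd`, seeded). The encoder is a bidirectional GRU (`u =
#' hidden_size / 2` units per direction, no bias terms), followed by a
#' structured self-attention layer producing `hops` weighted summaries of
#' the hidden states, a two-layer tanh projection to the final text
#' representation of length `r_rep`, and a two-layer ReLU + softmax head
#' mapping the representation onto the topic simplex.
#'
#' @param emb_dim Input embedding dimension.
#' @param r_topics Length of the topic posterior emitted by the head.
#' @param hidden_size Total bidirectional hidden size (2u); default 512.
#' @param r_rep Length of the text representation; default 64.
#' @param attn_dim Attention hidden size.
#' @param hops Number of attention rows (summaries); default 1.
#' @param proj_dim Projection hidden size (default `r_rep`).
#' @param head_dim Head hidden size (default `r_rep`).
#' @param init `"scaled"` (default) draws each weight matrix with the
#'   Glorot standard deviation `sqrt(2 / (fan_in + fan_out))`, which keeps
#'   signal magnitudes stable across layer widths; `"constant"` uses the
#'   fixed `init_sd` for every block.
#' @param init_sd Standard deviation used when `init = "constant"`.
#' @param seed Integer seed.
#' @return An `dsc_encoder_params` list of weight matrices plus the
#'   architecture constants.
#' @export
encoder_params <- function(emb_dim, r_topics, hidden_size = 512L,
                           r_rep = 64L, attn_dim = 64L, hops = 1L,
                           proj_dim = NULL, head_dim = NULL,
                           init = c("scaled", "constant"),
                           init_sd = 0.02, seed = 1L) {
  init <- match.arg(init)
  if (hidden_size %% 2 != 0) abort("hidden_size must be even (2u)")
  u <- hidden_size %/% 2L
  proj_dim <- proj_dim %||% r_rep
  head_dim <- head_dim %||% r_rep
  d <- emb_dim
  shapes <- list(
    fw_r = c(u, u + d), fw_z = c(u, u + d), fw_h = c(u, u + d),
    bw_r = c(u, u + d), bw_z = c(u, u + d), bw_h = c(u, u + d),
    attn_W1 = c(attn_dim, 2L * u), attn_W2 = c(hops, attn_dim),
    proj_W1 = c(hops * 2L * u, proj_dim), proj_W2 = c(r_rep, proj_dim),
    head_W1 = c(r_rep, head_dim), head_W2 = c(r_topics, head_dim)
  )
  weights <- with_seed(seed, {
    lapply(shapes, function(s) {
      sd <- if (init == "scaled") sqrt(2 / (s[1] + s[2])) else init_sd
      matrix(rnorm(prod(s), sd = sd), s[1], s[2])
    })
  })
  structure(
    c(weights,
      list(emb_dim = d, u = u, hops = hops, attn_dim = attn_dim,
           proj_dim = proj_dim, head_dim = head_dim, r_rep = r_rep,
           r_topics = r_topics, init = init, init_sd = init_sd,
           seed = seed)),
    class = "dsc_encoder_params"
  )
}

weight_names <- function() {
  c("fw_r", "fw_z", "fw_h", "bw_r", "bw_z", "bw_h",
    "attn_W1", "attn_W2", "proj_W1", "proj_W2", "head_W1", "head_W2")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU cell update
#'
#' Reference (single time step) implementation of the gated recurrent unit:
#' reset gate `r = sigmoid(W_r [h, x])`, update gate `z = sigmoid(W_z [h, x])`,
#' candidate `h~ = tanh(W_h [r * h, x])`, new state
#' `h' = (1 - z) * h + z * h~`.
#'
#' @param x_t Input vector (length `emb_dim`).
#' @param h_prev Previous hidden state (length `u`).
#' @param params Encoder parameters.
#' @param direction `"forward"` or `"backward"` (selects the weight set).
#' @return The updated hidden state (length `u`).
#' @export
gru_step <- function(x_t, h_prev, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (length(x_t) != params$emb_dim || length(h_prev) != params$u) {
    abort("gru_step: input/state lengths do not match the parameters")
  }
  W <- if (direction == "forward") {
    list(r = params$fw_r, z = params$fw_z, h = params$fw_h)
  } else {
    list(r = params$bw_r, z = params$bw_z, h = params$bw_h)
  }
  hx <- c(h_prev, x_t)
  r <- sigmoid(as.vector(W$r %*% hx))
  z <- sigmoid(as.vector(W$z %*% hx))
  htil <- tanh(as.vector(W$h %*% c(r * h_prev, x_t)))
  (1 - z) * h_prev + z * htil
}

#' Encode a weighted token sequence with the bidirectional GRU
#'
#' Runs the forward pass left-to-right and the backward pass right-to-left,
#' both from zero initial states, and concatenates the two states at every
#' position.
#'
#' @param fw A `k x emb_dim` fused feature matrix (one row per token).
#' @param params Encoder parameters.
#' @return The hidden-state matrix `H`, `k x 2u`.
#' @export
bigru_encode <- function(fw, params) {
  fw <- as.matrix(fw)
  k <- nrow(fw)
  if (k < 1) abort("cannot encode an empty sequence")
  u <- params$u
  H <- matrix(0, k, 2L * u)
  h <- numeric(u)
  for (t in seq_len(k)) {
    h <- gru_step(fw[t, ], h, params, "forward")
    H[t, seq_len(u)] <- h
  }
  h <- numeric(u)
  for (t in rev(seq_len(k))) {
    h <- gru_step(fw[t, ], h, params, "backward")
    H[t, u + seq_len(u)] <- h
  }
  H
}

#' Structured self-attention over hidden states
#'
#' Computes attention scores `Z = W2 tanh(W1 H^T)`, normalizes each of the
#' `hops` score rows over the k token positions with a softmax to give the
#' attention matrix `A`, forms the summary `Zhat = A H`, and projects the
#' flattened summary through a two-layer tanh map to the final text
#' representation `M`.
#'
#' @param H A `k x 2u` hidden-state matrix.
#' @param params Encoder parameters.
#' @return A list with `A` (`hops x k` attention matrix, rows sum to 1) and
#'   `M` (length `r_rep` representation).
#' @export
self_attend <- function(H, params) {
  H <- as.matrix(H)
  if (nrow(H) < 1) abort("self_attend: empty H")
  G <- tanh(params$attn_W1 %*% t(H))       # attn_dim x k
  Z <- params$attn_W2 %*% G                # hops x k
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  A <- E / rowSums(E)
  zhat <- A %*% H                          # hops x 2u
  zvec <- as.vector(t(zhat))               # flatten hop-major
  s <- tanh(as.vector(t(params$proj_W1) %*% zvec))
  M <- as.vector(params$proj_W2 %*% s)
  list(A = A, M = M)
}

#' Topic posterior of a text representation
#'
#' Two-layer head `softmax(W2 relu(W1^T M))` mapping the representation onto
#' the probability simplex over topics; the output is strictly positive and
#' sums to 1.
#'
#' @param M Text representation vector (length `r_rep`).
#' @param params Encoder parameters.
#' @return Numeric simplex vector of length `r_topics`.
#' @export
topic_head <- function(M, params) {
  s <- pmax(as.vector(t(params$head_W1) %*% M), 0)
  logits <- as.vector(params$head_W2 %*% s)
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Encode one document end to end
#'
#' Convenience wrapper chaining [bigru_encode()], [self_attend()] and
#' [topic_head()].
#'
#' @inheritParams bigru_encode
#' @return List with `H`, `A`, `M` and the topic posterior `D`.
#' @export
encode_document <- function(fw, params) {
  H <- bigru_encode(fw, params)
  att <- self_attend(H, params)
  list(H = H, A = att$A, M = att$M, D = topic_head(att$M, params))
}

# ---------------------------------------------------------------------------
# Batched forward/backward used by the training loop. Documents are padded to
# the longest length in the batch; masked positions carry the previous state
# unchanged in the forward pass and pass gradients through unchanged in the
# backward pass, so padding never influences any result.

gru_direction_forward <- function(X, mask, Wr, Wz, Wh) {
  steps <- length(X)
  B <- nrow(X[[1]])
  u <- nrow(Wr)
  Hprev <- matrix(0, B, u)
  cache <- vector("list", steps)
  states <- vector("list", steps)
  for (s in seq_len(steps)) {
    C <- cbind(Hprev, X[[s]])
    R <- sigmoid(C %*% t(Wr))
    Z <- sigmoid(C %*% t(Wz))
    Ct <- cbind(R * Hprev, X[[s]])
    Htil <- tanh(Ct %*% t(Wh))
    Hnew <- (1 - Z) * Hprev + Z * Htil
    m <- mask[, s]
    Hcur <- Hprev
    Hcur[m, ] <- Hnew[m, , drop = FALSE]
    cache[[s]] <- list(R = R, Z = Z, Htil = Htil, Hprev = Hprev, X = X[[s]])
    states[[s]] <- Hcur
    Hprev <- Hcur
  }
  list(states = states, cache = cache)
}

gru_direction_backward <- function(dstates, mask, cache, Wr, Wz, Wh) {
  steps <- length(dstates)
  B <- nrow(dstates[[1]])
  u <- nrow(Wr)
  gWr <- matrix(0, nrow(Wr), ncol(Wr))
  gWz <- gWr
  gWh <- gWr
  carry <- matrix(0, B, u)
  for (s in rev(seq_len(steps))) {
    cc <- cache[[s]]
    dh <- carry + dstates[[s]]
    m <- mask[, s]
    dZg <- dh * (cc$Htil - cc$Hprev)
    dHtil <- dh * cc$Z
    dh_prev <- dh * (1 - cc$Z)
    da <- dHtil * (1 - cc$Htil^2)
    da[!m, ] <- 0
    gWh <- gWh + crossprod(da, cbind(cc$R * cc$Hprev, cc$X))
    dRH <- (da %*% Wh)[, seq_len(u), drop = FALSE]
    dR <- dRH * cc$Hprev
    dh_prev <- dh_prev + dRH * cc$R
    dpr <- dR * cc$R * (1 - cc$R)
    dpr[!m, ] <- 0
    gWr <- gWr + crossprod(dpr, cbind(cc$Hprev, cc$X))
    dh_prev <- dh_prev + dpr %*% Wr[, seq_len(u), drop = FALSE]
    dpz <- dZg * cc$Z * (1 - cc$Z)
    dpz[!m, ] <- 0
    gWz <- gWz + crossprod(dpz, cbind(cc$Hprev, cc$X))
    dh_prev <- dh_prev + dpz %*% Wz[, seq_len(u), drop = FALSE]
    carry <- dh
    carry[m, ] <- dh_prev[m, , drop = FALSE]
  }
  list(gWr = gWr, gWz = gWz, gWh = gWh)
}

# Forward pass for a batch of fused sequences (list of k_b x d matrices).
# Returns M (B x r_rep), the attention summaries and a cache for backprop.
encoder_forward <- function(fws, params) {
  B <- length(fws)
  d <- params$emb_dim
  u <- params$u
  hops <- params$hops
  lens <- vapply(fws, nrow, 0L)
  kmax <- max(lens)
  mask <- outer(lens, seq_len(kmax), ">=")
  X <- lapply(seq_len(kmax), function(s) {
    out <- matrix(0, B, d)
    rows <- which(mask[, s])
    for (b in rows) out[b, ] <- fws[[b]][s, ]
    out
  })
  fwd <- gru_direction_forward(X, mask, params$fw_r, params$fw_z, params$fw_h)
  # backward direction: same recurrence processed from the last position
  Xr <- rev(X)
  maskr <- mask[, rev(seq_len(kmax)), drop = FALSE]
  bwd <- gru_direction_forward(Xr, maskr, params$bw_r, params$bw_z, params$bw_h)
  bwd_states <- rev(bwd$states)

  Hcat <- lapply(seq_len(kmax), function(s) cbind(fwd$states[[s]],
                                                  bwd_states[[s]]))
  # attention scores per position
  pre <- vector("list", kmax)
  zarr <- vector("list", kmax)
  for (s in seq_len(kmax)) {
    pre[[s]] <- tanh(Hcat[[s]] %*% t(params$attn_W1)) # B x attn_dim
    zarr[[s]] <- pre[[s]] %*% t(params$attn_W2)       # B x hops
  }
  # masked softmax over positions, per hop
  zmax <- Reduce(pmax, lapply(seq_len(kmax), function(s) {
    z <- zarr[[s]]
    z[!mask[, s], ] <- -Inf
    z
  }))
  Earr <- vector("list", kmax)
  Esum <- matrix(0, B, hops)
  for (s in seq_len(kmax)) {
    E <- exp(zarr[[s]] - zmax)
    E[!mask[, s], ] <- 0
    Earr[[s]] <- E
    Esum <- Esum + E
  }
  A <- lapply(Earr, function(E) E / Esum) # B x hops per position
  zhat <- matrix(0, B, hops * 2L * u)
  for (s in seq_len(kmax)) {
    for (r in seq_len(hops)) {
      cols <- (r - 1L) * 2L * u + seq_len(2L * u)
      zhat[, cols] <- zhat[, cols] + A[[s]][, r] * Hcat[[s]]
    }
  }
  Sp <- zhat %*% params$proj_W1
  G <- tanh(Sp)
  M <- G %*% t(params$proj_W2)
  list(M = M,
       cache = list(X = X, mask = mask, maskr = maskr, fwd = fwd, bwd = bwd,
                    Hcat = Hcat, pre = pre, A = A, zhat = zhat, G = G,
                    lens = lens))
}

head_forward <- function(M, params) {
  Sh <- M %*% params$head_W1
  Rh <- pmax(Sh, 0)
  logits <- Rh %*% t(params$head_W2)
  ex <- exp(logits - apply(logits, 1, max))
  D <- ex / rowSums(ex)
  list(D = D, logits = logits, cache = list(M = M, Sh = Sh, Rh = Rh))
}

# Backward pass. dM_extra: gradient of the loss w.r.t. M from terms other
# than the head (B x r_rep); dlogits: gradient w.r.t. the head logits
# (B x r_topics), zero matrix when the topic loss is off.
encoder_backward <- function(params, fwd_out, head_out, dM_extra, dlogits) {
  cache <- fwd_out$cache
  B <- nrow(fwd_out$M)
  u <- params$u
  hops <- params$hops
  kmax <- length(cache$X)
  grads <- list()

  hc <- head_out$cache
  dRh <- dlogits %*% params$head_W2
  grads$head_W2 <- crossprod(dlogits, hc$Rh)
  dSh <- dRh * (hc$Sh > 0)
  grads$head_W1 <- crossprod(hc$M, dSh)
  dM <- dM_extra + dSh %*% t(params$head_W1)

  grads$proj_W2 <- crossprod(dM, cache$G)
  dG <- dM %*% params$proj_W2
  dSp <- dG * (1 - cache$G^2)
  grads$proj_W1 <- crossprod(cache$zhat, dSp)
  dzhat <- dSp %*% t(params$proj_W1)

  grads$attn_W1 <- matrix(0, nrow(params$attn_W1), ncol(params$attn_W1))
  grads$attn_W2 <- matrix(0, nrow(params$attn_W2), ncol(params$attn_W2))
  dHcat <- vector("list", kmax)
  dA <- vector("list", kmax)
  for (s in seq_len(kmax)) {
    dHcat[[s]] <- matrix(0, B, 2L * u)
    dA[[s]] <- matrix(0, B, hops)
    for (r in seq_len(hops)) {
      cols <- (r - 1L) * 2L * u + seq_len(2L * u)
      dz_r <- dzhat[, cols, drop = FALSE]
      dA[[s]][, r] <- rowSums(dz_r * cache$Hcat[[s]])
      dHcat[[s]] <- dHcat[[s]] + cache$A[[s]][, r] * dz_r
    }
  }
  # softmax backprop over positions (per hop): dz = A * (dA - sum_t A dA)
  Ssum <- matrix(0, B, hops)
  for (s in seq_len(kmax)) Ssum <- Ssum + cache$A[[s]] * dA[[s]]
  for (s in seq_len(kmax)) {
    dz <- cache$A[[s]] * (dA[[s]] - Ssum) # B x hops, zero at padding
    grads$attn_W2 <- grads$attn_W2 + crossprod(dz, cache$pre[[s]])
    dpre <- (dz %*% params$attn_W2) * (1 - cache$pre[[s]]^2)
    dpre[!cache$mask[, s], ] <- 0
    grads$attn_W1 <- grads$attn_W1 + crossprod(dpre, cache$Hcat[[s]])
    dHcat[[s]] <- dHcat[[s]] + dpre %*% params$attn_W1
    dHcat[[s]][!cache$mask[, s], ] <- 0
  }

  dfwd <- lapply(dHcat, function(m) m[, seq_len(u), drop = FALSE])
  dbwd <- lapply(dHcat, function(m) m[, u + seq_len(u), drop = FALSE])
  gf <- gru_direction_backward(dfwd, cache$mask, cache$fwd$cache,
                               params$fw_r, params$fw_z, params$fw_h)
  gb <- gru_direction_backward(rev(dbwd), cache$maskr, cache$bwd$cache,
                               params$bw_r, params$bw_z, params$bw_h)
  grads$fw_r <- gf$gWr; grads$fw_z <- gf$gWz; grads$fw_h <- gf$gWh
  grads$bw_r <- gb$gWr; grads$bw_z <- gb$gWz; grads$bw_h <- gb$gWh
  grads[weight_names()]
}

# Encode an entire corpus in batches; returns the B x r_rep matrix M.
encode_corpus <- function(fws, params, batch_size = 256L) {
  n <- length(fws)
  out <- matrix(0, n, params$r_rep)
  start <- 1L
  while (start <= n) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- encoder_forward(fws[idx], params)$M
    start <- start + batch_size
  }
  out
}
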