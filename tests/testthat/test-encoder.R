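zeroed_params <- function(params) {
  for (nm in dsclust:::weight_names()) params[[nm]] <- params[[nm]] * 0
  params
}

small_params <- function(seed = 5, emb_dim = 2, u2 = 4, r_rep = 3,
                         r_topics = 2, hops = 1, sd = 0.6) {
  encoder_params(emb_dim = emb_dim, r_topics = r_topics, hidden_size = u2,
                 r_rep = r_rep, attn_dim = 3, hops = hops,
                 init = "constant", init_sd = sd, seed = seed)
}

test_that("the GRU cell satisfies its fixed points and the scalar oracle", {
  p <- zeroed_params(small_params())
  h <- c(0.4, -0.2)
  x <- c(1, 2)
  # zero weights: r = z = 0.5, candidate 0, so h' = 0.5 h
  expect_equal(gru_step(x, h, p, "forward"), 0.5 * h)
  expect_equal(gru_step(x, numeric(2), p, "forward"), c(0, 0))

  p2 <- small_params(seed = 9)
  p2$fw_r <- matrix(c(1, -1, 0.5, 0.25,
                      0, 2, -0.5, 1), 2, 4, byrow = TRUE)
  p2$fw_z <- matrix(c(0.5, 0, 1, -1,
                      1, 1, 0, 0.5), 2, 4, byrow = TRUE)
  p2$fw_h <- matrix(c(-1, 0.5, 1, 0,
                      0.25, -0.25, 0.5, 2), 2, 4, byrow = TRUE)
  got <- gru_step(x, h, p2, "forward")
  want <- gru_step_oracle(x, h, p2$fw_r, p2$fw_z, p2$fw_h)
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(gru_step(c(1, 2, 3), h, p2), "lengths")
})

test_that("the bidirectional encoder respects shapes and symmetries", {
  p <- small_params(seed = 2)
  # k = 1: both directions see the same single input
  H1 <- bigru_encode(matrix(c(1, -1), 1, 2), p)
  expect_equal(dim(H1), c(1, 4))

  # palindromic input with shared direction weights: reversing the document
  # reverses the rows and swaps the direction halves
  p$bw_r <- p$fw_r; p$bw_z <- p$fw_z; p$bw_h <- p$fw_h
  fw <- matrix(rnorm(10), 5, 2)
  H <- bigru_encode(fw, p)
  Hrev <- bigru_encode(fw[5:1, ], p)
  expect_equal(Hrev, H[5:1, c(3, 4, 1, 2)], tolerance = 1e-12)

  # zero weights: states never leave zero
  expect_true(all(bigru_encode(fw, zeroed_params(p)) == 0))
})

test_that("self-attention normalizes over words and matches the scalar oracle", {
  p <- small_params(seed = 3, hops = 2)
  H <- matrix(rnorm(12), 3, 4)
  att <- self_attend(H, p)
  expect_equal(rowSums(att$A), c(1, 1), tolerance = 1e-6)
  expect_length(att$M, 3)

  # identical rows: the convex combination returns the common row
  Hc <- matrix(rep(c(1, -2, 0.5, 3), each = 4), 4, 4)
  attc <- self_attend(Hc, p)
  zhat <- attc$A %*% Hc
  expect_equal(unname(zhat[1, ]), c(1, -2, 0.5, 3), tolerance = 1e-9)
  expect_equal(unname(zhat[2, ]), c(1, -2, 0.5, 3), tolerance = 1e-9)

  # k = 2, u = 1: fixed small weights against a step-by-step evaluation
  ps <- encoder_params(emb_dim = 2, r_topics = 2, hidden_size = 2,
                       r_rep = 2, attn_dim = 2, hops = 1,
                       init = "constant", init_sd = 0.5, seed = 8)
  Hs <- matrix(c(0.3, -0.1, 0.2, 0.4), 2, 2)
  want <- self_attend_oracle(Hs, ps$attn_W1, ps$attn_W2, ps$proj_W1,
                             ps$proj_W2)
  got <- self_attend(Hs, ps)
  expect_equal(got$A, want$A, tolerance = 1e-9)
  expect_equal(got$M, want$M, tolerance = 1e-9)
})

test_that("the topic head emits a strictly positive simplex vector", {
  p <- small_params(seed = 4)
  expect_equal(topic_head(c(1, 2, 3), zeroed_params(p)), c(0.5, 0.5))
  d <- topic_head(c(-1, 0.5, 2), p)
  expect_equal(sum(d), 1, tolerance = 1e-6)
  expect_true(all(d > 0))

  # engineered logits (ln 3, 0) give the closed-form posterior (0.75, 0.25)
  pe <- encoder_params(emb_dim = 2, r_topics = 2, hidden_size = 2,
                       r_rep = 1, head_dim = 1, seed = 1)
  pe$head_W1 <- matrix(1, 1, 1)
  pe$head_W2 <- matrix(c(log(3), 0), 2, 1)
  expect_equal(topic_head(1, pe), c(0.75, 0.25), tolerance = 1e-9)
})

test_that("the shape chain holds for every document length and init is seeded", {
  p <- small_params(seed = 6)
  for (k in c(1, 2, 5, 9)) {
    fw <- matrix(rnorm(2 * k), k, 2)
    out <- encode_document(fw, p)
    expect_equal(dim(out$H), c(k, 4))
    expect_length(out$M, 3)
    expect_length(out$D, 2)
    expect_equal(sum(out$D), 1, tolerance = 1e-6)
  }
  expect_identical(small_params(seed = 7), small_params(seed = 7))
})

test_that("batched encoding agrees with per-document encoding", {
  p <- small_params(seed = 10)
  set.seed(33)
  fws <- lapply(c(1, 4, 2, 6), function(k) matrix(rnorm(2 * k), k, 2))
  fwd <- dsclust:::encoder_forward(fws, p)
  for (b in seq_along(fws)) {
    one <- encode_document(fws[[b]], p)
    expect_equal(unname(fwd$M[b, ]), one$M, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  p <- small_params(seed = 12, sd = 0.6)
  fws <- lapply(c(3, 1, 4), function(k) matrix(rnorm(2 * k), k, 2))
  Tb <- t(vapply(1:3, function(i) random_simplex(2), numeric(2)))
  centroids <- matrix(rnorm(6), 2, 3)
  assign <- c(1L, 2L, 1L)
  alpha <- 0.3
  bc <- list(centroids = centroids, assign = assign)

  loss_fn <- function(pp) {
    fwd <- dsclust:::encoder_forward(fws, pp)
    hd <- dsclust:::head_forward(fwd$M, pp)
    alpha * cluster_loss(fwd$M, bc) + topic_loss(Tb, hd$D)
  }
  fwd <- dsclust:::encoder_forward(fws, p)
  hd <- dsclust:::head_forward(fwd$M, p)
  grads <- dsclust:::encoder_backward(
    p, fwd, hd, alpha * dsclust:::cluster_loss_grad(fwd$M, bc), hd$D - Tb
  )
  eps <- 1e-5
  for (nm in dsclust:::weight_names()) {
    idx <- sample(length(p[[nm]]), min(5, length(p[[nm]])))
    for (i in idx) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (loss_fn(p_hi) - loss_fn(p_lo)) / (2 * eps)
      rel <- abs(num - grads[[nm]][i]) /
        max(abs(num) + abs(grads[[nm]][i]), 1)
      expect_lt(rel, 1e-4)
    }
  }
})
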