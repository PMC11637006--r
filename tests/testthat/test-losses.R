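test_that("the climbing schedule ramps linearly and clamps", {
  expect_equal(alpha_schedule(0, 32), 0)
  expect_equal(alpha_schedule(32, 32), 0.3)
  expect_equal(alpha_schedule(64, 32), 0.3)
  expect_equal(alpha_schedule(16, 32), 0.15)
  expect_equal(alpha_schedule(3, 10, alpha_max = 1), 0.3)
  expect_error(alpha_schedule(1, 0), "T_ramp")
})

test_that("batch k-means recovers separated groups and degenerate cases", {
  x <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  fit <- batch_kmeans(x, 2, seed = 1)
  expect_equal(sort(unname(table(fit$assign))), c(5, 5), ignore_attr = TRUE)
  expect_equal(fit$inertia, 0)
  expect_setequal(fit$centroids[, 1], c(0, 10))

  # K = m: every point its own centroid
  y <- matrix(rnorm(12), 4, 3)
  fit2 <- batch_kmeans(y, 4, seed = 2)
  expect_equal(fit2$inertia, 0, tolerance = 1e-12)
  expect_equal(sort(fit2$assign), 1:4)

  expect_error(batch_kmeans(y, 5, seed = 1), "cannot support")
})

test_that("Lloyd iterations agree with the reference k-means on a shared init", {
  set.seed(77)
  x <- matrix(rnorm(40), 20, 2)
  init <- x[c(3, 11), ]
  ours <- dsclust:::lloyd(x, init)
  ref <- suppressWarnings(stats::kmeans(x, centers = init,
                                        algorithm = "Lloyd", iter.max = 100))
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-9)
  expect_equal(unname(ours$centers[ours$assign, ]),
               unname(ref$centers[ref$cluster, ]), tolerance = 1e-9)
})

test_that("cluster loss is the summed squared distance to assigned centroids", {
  feats <- matrix(c(0, 2), 2, 1)
  bc <- list(centroids = matrix(1, 1, 1), assign = c(1L, 1L))
  expect_equal(cluster_loss(feats, bc), 2)

  # features sitting on their centroids give zero loss
  cent <- matrix(rnorm(6), 3, 2)
  bc2 <- list(centroids = cent, assign = c(2L, 1L, 3L, 2L))
  expect_equal(cluster_loss(cent[bc2$assign, ], bc2), 0)

  # random batch vs an independent loop-based recomputation
  set.seed(5)
  f <- matrix(rnorm(40), 10, 4)
  bc3 <- batch_kmeans(f, 3, seed = 9)
  manual <- 0
  for (i in 1:10) {
    manual <- manual + sum((f[i, ] - bc3$centroids[bc3$assign[i], ])^2)
  }
  expect_equal(cluster_loss(f, bc3), manual, tolerance = 1e-9)

  # literal all-centroids variant: double sum over samples and centroids
  manual_all <- 0
  for (i in 1:10) for (k in 1:3) {
    manual_all <- manual_all + sum((f[i, ] - bc3$centroids[k, ])^2)
  }
  expect_equal(cluster_loss(f, bc3, variant = "all_centroids"), manual_all,
               tolerance = 1e-9)
})

test_that("cluster loss gradients match numeric differentiation", {
  set.seed(6)
  f <- matrix(rnorm(12), 4, 3)
  bc <- batch_kmeans(f, 2, seed = 3)
  for (variant in c("assigned", "all_centroids")) {
    g <- dsclust:::cluster_loss_grad(f, bc, variant)
    eps <- 1e-6
    for (i in sample(length(f), 6)) {
      fh <- f; fh[i] <- fh[i] + eps
      fl <- f; fl[i] <- fl[i] - eps
      num <- (cluster_loss(fh, bc, variant) -
                cluster_loss(fl, bc, variant)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("the topic loss is a proper KL divergence", {
  T_ <- rbind(c(0.2, 0.8), c(0.5, 0.5))
  expect_equal(topic_loss(T_, T_), 0)
  expect_equal(topic_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2))
  # non-negativity over random simplex pairs
  set.seed(8)
  for (i in 1:100) {
    t <- random_simplex(4)
    d <- random_simplex(4)
    expect_gte(topic_loss(rbind(t), rbind(d)), 0)
  }
  expect_error(topic_loss(T_, rbind(c(1, 0, 0))), "dimensions")
})

test_that("the joint loss is the alpha-weighted sum", {
  expect_equal(joint_loss(5, 0.7, 0), 0.7)
  expect_equal(joint_loss(2.0, 0.5, 0.3), 1.1)
  lt <- 0.4
  a <- 0.25
  expect_equal(joint_loss(6, lt, a) - joint_loss(2, lt, a), a * 4)
  expect_error(joint_loss(1, 1, -0.1), "alpha")
})
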