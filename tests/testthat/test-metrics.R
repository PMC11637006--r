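test_that("optimal-mapping accuracy handles canonical cases", {
  expect_equal(clustering_accuracy(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(clustering_accuracy(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.5)
  expect_equal(clustering_accuracy(c(0, 1, 2), c(0, 0, 0)), 1 / 3)
  expect_error(clustering_accuracy(c(1, 2), c(1, 2, 3)), "length")
})

test_that("accuracy equals the brute-force optimum over injective mappings", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    kg <- sample(2:6, 1)
    kp <- sample(2:6, 1)
    gold <- sample(kg, n, replace = TRUE)
    pred <- sample(kp, n, replace = TRUE)
    expect_equal(clustering_accuracy(gold, pred), brute_force_acc(gold, pred))
  }
})

test_that("NMI follows the arithmetic-mean normalization and its edge cases", {
  expect_equal(nmi(c(0, 0, 1, 1), c(5, 5, 9, 9)), 1.0)
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0.0)
  expect_equal(nmi(c(2, 2, 2), c(7, 7, 7)), 1.0)
  # 2x2 hand computation
  gold <- c(0, 0, 1, 1)
  pred <- c(0, 1, 1, 1)
  expect_equal(nmi(gold, pred), nmi_oracle(gold, pred), tolerance = 1e-12)
})

test_that("ARI matches the pair-count formula and is centred at zero", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  gold <- c(0, 0, 1, 1)
  pred <- c(0, 1, 0, 1)
  expect_equal(ari(gold, pred), ari_oracle(gold, pred), tolerance = 1e-12)

  set.seed(202)
  vals <- replicate(200, {
    ari(sample(3, 50, replace = TRUE), sample(3, 50, replace = TRUE))
  })
  expect_gt(mean(vals), -0.05)
  expect_lt(mean(vals), 0.05)
})

test_that("metrics agree with independent implementations on random instances", {
  skip_if_not_installed("mclust")
  set.seed(303)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    gold <- sample(sample(2:5, 1), n, replace = TRUE)
    pred <- sample(sample(2:5, 1), n, replace = TRUE)
    expect_equal(nmi(gold, pred), nmi_oracle(gold, pred), tolerance = 1e-9)
    expect_equal(ari(gold, pred), ari_oracle(gold, pred), tolerance = 1e-9)
    expect_equal(ari(gold, pred),
                 mclust::adjustedRandIndex(gold, pred), tolerance = 1e-9)
    expect_equal(clustering_f1(gold, pred, "pairwise"),
                 pairwise_f1_oracle(gold, pred), tolerance = 1e-9)
  }
})

test_that("F1 variants satisfy identity and the enumerated pair example", {
  expect_equal(clustering_f1(c(0, 0, 1), c(0, 0, 1), "macro"), 1.0)
  expect_equal(clustering_f1(c(0, 0, 1), c(0, 0, 1), "pairwise"), 1.0)
  # single predicted cluster vs two gold classes: recall 1, precision 2/6
  expect_equal(clustering_f1(c(0, 0, 1, 1), c(1, 1, 1, 1), "pairwise"), 0.5)
  expect_equal(clustering_f1(c(0, 0, 1, 1), c(0, 1, 0, 1), "pairwise"),
               pairwise_f1_oracle(c(0, 0, 1, 1), c(0, 1, 0, 1)))
})

test_that("all metrics are invariant under relabeling of the prediction", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    gold <- sample(3, n, replace = TRUE)
    pred <- sample(4, n, replace = TRUE)
    perm <- sample(4)
    pred2 <- perm[pred]
    expect_equal(clustering_accuracy(gold, pred),
                 clustering_accuracy(gold, pred2))
    expect_equal(nmi(gold, pred), nmi(gold, pred2))
    expect_equal(ari(gold, pred), ari(gold, pred2))
    expect_equal(clustering_f1(gold, pred, "macro"),
                 clustering_f1(gold, pred2, "macro"))
    expect_equal(clustering_f1(gold, pred, "pairwise"),
                 clustering_f1(gold, pred2, "pairwise"))
  }
})

test_that("the metrics report carries every indicator and the contingency table", {
  rep_ <- evaluate_clustering(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(rep_$acc, 1)
  expect_equal(rep_$nmi, 1)
  expect_equal(rep_$ari, 1)
  expect_equal(rep_$f1_macro, 1)
  expect_equal(rep_$f1_pairwise, 1)
  expect_equal(rep_$n, 4)
  tab <- attr(rep_, "contingency")
  expect_equal(sum(tab), 4)
  expect_equal(unname(rowSums(tab)), c(2, 2))
})
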