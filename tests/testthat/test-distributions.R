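test_that("initialization gives uniform simplex rows and rejects K < 2", {
  M <- init_distributions(2)
  expect_equal(M$entries, matrix(0.5, 2, 2))
  M4 <- init_distributions(4, "unlabeled")
  expect_true(all(M4$entries == 0.25))
  expect_identical(M4$role, "unlabeled")
  expect_no_error(validate_distribution(M4))
  expect_error(init_distributions(1), "integer >= 2")
})

test_that("labeled EMA update is a convex combination toward the class-conditional mean", {
  set.seed(1)
  K <- 3
  M <- random_class_dist(K, "labeled")
  probs <- random_prob_map(30, K)
  labels <- sample(0:(K - 1), 30, replace = TRUE)

  # alpha = 1 leaves the matrix untouched
  M1 <- update_labeled_distribution(M, probs, labels, ema_config(alpha = 1))
  expect_equal(M1$entries, M$entries)

  # alpha = 0 replaces each present row by the batch conditional mean
  M0 <- update_labeled_distribution(M, probs, labels, ema_config(alpha = 0))
  for (i in 0:(K - 1)) {
    v <- colMeans(probs$values[labels == i, , drop = FALSE])
    expect_equal(M0$entries[i + 1, ], v)
  }

  # general alpha: updated row on the segment between old row and mean
  Mh <- update_labeled_distribution(M, probs, labels,
                                    ema_config(alpha = 0.7))
  for (i in 0:(K - 1)) {
    v <- colMeans(probs$values[labels == i, , drop = FALSE])
    expect_equal(Mh$entries[i + 1, ], 0.7 * M$entries[i + 1, ] + 0.3 * v)
  }
  expect_no_error(validate_distribution(Mh))
  # input not mutated
  expect_equal(sum(M$entries), K, tolerance = 1e-9)
})

test_that("rows of classes absent from a labeled batch stay unchanged", {
  set.seed(2)
  K <- 4
  M <- random_class_dist(K, "labeled")
  probs <- random_prob_map(12, K)
  labels <- rep(c(0L, 2L), 6)  # classes 1 and 3 absent
  up <- update_labeled_distribution(M, probs, labels,
                                    ema_config(alpha = 0.5))
  expect_equal(up$entries[2, ], M$entries[2, ])
  expect_equal(up$entries[4, ], M$entries[4, ])
  expect_false(isTRUE(all.equal(up$entries[1, ], M$entries[1, ])))
})

test_that("labeled update validates shapes and label range", {
  M <- init_distributions(3)
  probs <- random_prob_map(5, 3)
  expect_error(update_labeled_distribution(M, probs, c(0, 1)), "mismatch")
  expect_error(update_labeled_distribution(M, probs, c(0, 1, 2, 3, 1)),
               "labels must lie")
  aligned <- random_prob_map(5, 3, aligned = TRUE)
  expect_error(update_labeled_distribution(M, aligned, rep(0, 5)),
               "unaligned")
})

test_that("EMA recursion under a constant batch mean matches the closed form", {
  # oracle: iterate the scalar recursion; closed form p + alpha^n (r0 - p)
  K <- 2
  p_vec <- c(0.3, 0.7)
  probs <- prob_map(matrix(p_vec, 4, K, byrow = TRUE))
  labels <- rep(0L, 4)
  for (alpha in c(0, 0.5, 0.99, 1)) {
    M <- init_distributions(K, "labeled")
    r0 <- M$entries[1, ]
    for (n in c(1, 7, 50)) {
      Mn <- M
      cfg <- ema_config(alpha = alpha)
      for (it in seq_len(n))
        Mn <- update_labeled_distribution(Mn, probs, labels, cfg)
      closed <- p_vec + alpha^n * (r0 - p_vec)
      oracle <- c(iterate_ema(r0[1], p_vec[1], alpha, n),
                  iterate_ema(r0[2], p_vec[2], alpha, n))
      expect_equal(Mn$entries[1, ], closed, tolerance = 1e-9)
      expect_equal(Mn$entries[1, ], oracle, tolerance = 1e-12)
    }
  }
})

test_that("unlabeled update groups by pseudo-class and synthesizes absent rows", {
  # worked absent-class example, alpha = 1 so present rows stay put
  Ml <- init_distributions(2, "labeled")
  Ml$entries <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
  Mu <- init_distributions(2, "unlabeled")
  Mu$entries <- matrix(c(0.8, 0.2, 0.25, 0.75), 2, byrow = TRUE)
  probs <- prob_map(matrix(c(0.9, 0.1), 1))  # pseudo-class 0 only
  up <- update_unlabeled_distribution(Mu, Ml, probs, ema_config(alpha = 1))
  # oracle: direct scalar evaluation of the absent-class branch
  ratio <- c(mean(c(0.8 / 0.7, 0.25 / 0.2)),
             mean(c(0.2 / 0.3, 0.75 / 0.8)))
  v <- c(0.2, 0.8) * ratio
  expect_equal(up$entries[2, ], v / sum(v), tolerance = 1e-6)
  expect_equal(up$entries[1, ], Mu$entries[1, ])  # present row, alpha = 1

  # alpha = 0: present row equals the batch conditional mean
  batch <- prob_map(matrix(c(0.9, 0.1,
                             0.8, 0.2,
                             0.7, 0.3,
                             0.6, 0.4), 4, byrow = TRUE))
  up0 <- update_unlabeled_distribution(Mu, Ml, batch, ema_config(alpha = 0))
  expect_equal(up0$entries[1, ], c(0.75, 0.25))
  expect_equal(up0$entries[2, ], v / sum(v), tolerance = 1e-6)
})

test_that("unlabeled update with all classes present and alpha = 1 is a no-op", {
  set.seed(3)
  K <- 3
  Ml <- random_class_dist(K, "labeled")
  Mu <- random_class_dist(K, "unlabeled")
  # one confident pixel per class
  V <- diag(K) * 0.9 + 0.1 / K
  probs <- prob_map(V / rowSums(V))
  up <- update_unlabeled_distribution(Mu, Ml, probs, ema_config(alpha = 1))
  expect_equal(up$entries, Mu$entries)
  # K mismatch rejected
  expect_error(
    update_unlabeled_distribution(Mu, random_class_dist(4, "labeled"),
                                  probs),
    "number of classes")
})

test_that("simplex invariant survives long randomized mixed update sequences", {
  set.seed(4)
  for (K in c(2, 5)) {
    Ml <- init_distributions(K, "labeled")
    Mu <- init_distributions(K, "unlabeled")
    cfg <- ema_config(alpha = 0.9)
    for (it in 1:100) {
      n <- sample(3:20, 1)
      probs <- random_prob_map(n, K)
      labels <- sample(0:(K - 1), n, replace = TRUE,
                       prob = 0.5^(1:K))  # imbalanced, classes often absent
      Ml <- update_labeled_distribution(Ml, probs, labels, cfg)
      Mu <- update_unlabeled_distribution(Mu, Ml, random_prob_map(n, K),
                                          cfg)
      expect_no_error(validate_distribution(Ml))
      expect_no_error(validate_distribution(Mu))
    }
  }
})

test_that("temperature is 1 - diagonal, clamped to [tau_min, 1]", {
  Ml <- init_distributions(3, "labeled")
  Ml$entries[1, ] <- c(0.6, 0.3, 0.1)
  Ml$entries[2, ] <- c(0, 1, 0)
  Ml$entries[3, ] <- c(1, 0, 0)
  cfg <- ema_config(tau_min = 0.05)
  expect_equal(compute_temperature(Ml, 0, cfg), 0.4)
  expect_equal(compute_temperature(Ml, 1, cfg), 0.05)  # 1 - 1 clamped up
  expect_equal(compute_temperature(Ml, 2, cfg), 1)     # 1 - 0
  expect_error(compute_temperature(Ml, 3, cfg), "class_index")
  expect_error(compute_temperature(Ml, -1, cfg), "class_index")
})

test_that("alignment matches the scalar oracle and is the identity under uniform matrices", {
  # worked K = 2 example: direct scalar evaluation of the transformation
  Ml <- init_distributions(2, "labeled")
  Ml$entries <- matrix(c(0.6, 0.4, 0.5, 0.5), 2, byrow = TRUE)
  Mu <- init_distributions(2, "unlabeled")
  Mu$entries <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, byrow = TRUE)
  p <- prob_map(matrix(c(0.7, 0.3), 1))
  cfg <- ema_config()
  tau0 <- 1 - 0.6
  w <- c(0.6, 0.4)^tau0 / (c(0.8, 0.2) + cfg$epsilon)
  expected <- (c(0.7, 0.3) * w) / sum(c(0.7, 0.3) * w)
  out <- align_prediction(p, Ml, Mu, cfg)
  expect_equal(out$values[1, ], expected, tolerance = 1e-9)
  expect_equal(out$values[1, ], c(0.4068964, 0.5931036), tolerance = 1e-6)
  expect_true(out$aligned)

  # uniform matrices: identity to 1e-9 for every pixel
  set.seed(5)
  for (K in c(2, 4, 6)) {
    probs <- random_prob_map(50, K)
    out <- align_prediction(probs, init_distributions(K, "labeled"),
                            init_distributions(K, "unlabeled"), cfg)
    expect_equal(out$values, probs$values, tolerance = 1e-9)
  }
})

test_that("aligned outputs are normalized and deterministic", {
  set.seed(6)
  K <- 5
  Ml <- random_class_dist(K, "labeled")
  Mu <- random_class_dist(K, "unlabeled")
  probs <- random_prob_map(200, K)
  out1 <- align_prediction(probs, Ml, Mu)
  out2 <- align_prediction(probs, Ml, Mu)
  expect_identical(out1$values, out2$values)  # bit-identical, pure
  expect_true(all(abs(rowSums(out1$values) - 1) < 1e-6))
  expect_true(all(out1$values >= 0))
})

test_that("alignment weakly favors class j as Ml[i, j] grows", {
  # raising the j-entry of the argmax class's labeled row (others fixed)
  # must weakly increase the aligned probability of class j
  Mu <- init_distributions(3, "unlabeled")
  p <- prob_map(matrix(c(0.6, 0.3, 0.1), 1))
  cfg <- ema_config()
  vals <- sapply(seq(0.05, 0.9, by = 0.05), function(mij) {
    Ml <- init_distributions(3, "labeled")
    # pre-normalization semantics: entry j grows, the rest of the row and
    # the diagonal (hence the temperature) stay fixed
    Ml$entries[1, ] <- c(0.3, mij, 0.1)
    align_prediction(p, Ml, Mu, cfg)$values[1, 2]
  })
  expect_true(all(diff(vals) > -1e-12))
})

test_that("distribution JSON round trip is lossless", {
  set.seed(7)
  M <- random_class_dist(4, "unlabeled")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_distribution(M, path)
  back <- read_distribution(path)
  expect_equal(back$entries, M$entries, tolerance = 1e-12)
  expect_identical(back$role, "unlabeled")
  expect_identical(back$num_classes, 4L)
})
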