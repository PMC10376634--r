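make_fixed_batch <- function(K = 4, seed = 40) {
  set.seed(seed)
  img_l <- matrix(runif(16 * 16), 16, 16)
  img_u <- matrix(runif(16 * 16), 16, 16)
  list(Xl = pixel_features(img_l),
       yl = sample(0:(K - 1), 256, replace = TRUE),
       Xu = pixel_features(img_u))
}

# run a few warm-up iterations so the state is no longer at its uniform
# initialization (otherwise some switches coincide trivially)
warmed_state <- function(config, batch, n = 5) {
  state <- init_train_state(config)
  for (i in seq_len(n)) state <- run_iteration(state, batch, config)$state
  state
}

test_that("training runs are bit-identical under identical config and seeds", {
  b <- tiny_bundle()
  cfg <- train_config(max_iterations = 25, val_interval = 10,
                      batch_labeled = 1, batch_unlabeled = 2)
  val <- list(images = b$test$images, masks = b$test$masks)
  f1 <- train(cfg, b$labeled, b$unlabeled, val)
  f2 <- train(cfg, b$labeled, b$unlabeled, val)
  expect_identical(f1$log$iterations, f2$log$iterations)
  expect_identical(f1$log$validation, f2$log$validation)
  expect_identical(f1$model1$params, f2$model1$params)
})

test_that("disabling alignment changes only the aligned maps and pseudo-labels", {
  cfg_on <- train_config(max_iterations = 20, alpha = 0.5)
  cfg_off <- train_config(max_iterations = 20, alpha = 0.5,
                          use_alignment = FALSE)
  batch <- make_fixed_batch()
  state <- warmed_state(cfg_on, batch)
  a_on <- run_iteration(state, batch, cfg_on)$artifacts
  a_off <- run_iteration(state, batch, cfg_off)$artifacts
  # upstream artifacts identical: raw predictions and distribution updates
  expect_identical(a_on$raw_labeled1$values, a_off$raw_labeled1$values)
  expect_identical(a_on$raw_unlabeled1$values, a_off$raw_unlabeled1$values)
  expect_identical(a_on$raw_unlabeled2$values, a_off$raw_unlabeled2$values)
  # downstream: aligned maps (hence pseudo-labels/confidences) differ
  expect_false(identical(a_on$aligned1$values, a_off$aligned1$values))
  expect_false(identical(a_on$pseudo1$confidences,
                         a_off$pseudo1$confidences))
  # with alignment off the "aligned" map is the raw prediction
  expect_identical(a_off$aligned1$values, a_off$raw_unlabeled1$values)
})

test_that("disabling the over-expectation filter changes only the accept masks", {
  cfg_on <- train_config(max_iterations = 20, alpha = 0.5)
  cfg_off <- train_config(max_iterations = 20, alpha = 0.5, use_oe = FALSE)
  batch <- make_fixed_batch()
  state <- warmed_state(cfg_on, batch)
  a_on <- run_iteration(state, batch, cfg_on)$artifacts
  a_off <- run_iteration(state, batch, cfg_off)$artifacts
  expect_identical(a_on$raw_unlabeled1$values, a_off$raw_unlabeled1$values)
  expect_identical(a_on$aligned1$values, a_off$aligned1$values)
  expect_identical(a_on$pseudo1$labels, a_off$pseudo1$labels)
  expect_identical(a_on$pseudo1$confidences, a_off$pseudo1$confidences)
  expect_identical(a_on$pseudo2$labels, a_off$pseudo2$labels)
  # masks differ: with the filter off every pixel is accepted
  expect_true(all(a_off$pseudo1$accept_mask))
  expect_true(all(a_off$pseudo2$accept_mask))
  expect_false(all(a_on$pseudo1$accept_mask))
})

test_that("with alignment and filtering off, Lu is the plain CPS loss of the logged maps", {
  cfg <- train_config(max_iterations = 20, use_alignment = FALSE,
                      use_oe = FALSE)
  batch <- make_fixed_batch()
  state <- warmed_state(cfg, batch)
  a <- run_iteration(state, batch, cfg)$artifacts
  # offline recomputation from the recorded intermediates
  lab1 <- max.col(a$raw_unlabeled1$values, ties.method = "first") - 1L
  lab2 <- max.col(a$raw_unlabeled2$values, ties.method = "first") - 1L
  lu_offline <- cps_loss(a$raw_unlabeled1, lab2) +
    cps_loss(a$raw_unlabeled2, lab1)
  expect_equal(a$losses$unsupervised, lu_offline, tolerance = 1e-12)
})

test_that("a zero static threshold reproduces the no-filter run", {
  b <- tiny_bundle()
  cfg0 <- train_config(max_iterations = 15, static_threshold = 0)
  cfg_no <- train_config(max_iterations = 15, use_oe = FALSE)
  f0 <- train(cfg0, b$labeled, b$unlabeled)
  fno <- train(cfg_no, b$labeled, b$unlabeled)
  expect_equal(f0$log$iterations$unsupervised,
               fno$log$iterations$unsupervised, tolerance = 1e-12)
})

test_that("supervised-only training learns a separable two-class task", {
  spec <- synthetic_spec(num_classes = 2, num_images = 8, num_test = 4,
                         image_size = c(20, 20), labeled_fraction = 0.5,
                         noise_sigma = 0.05, image_offset_sd = 0, seed = 6)
  b <- generate_bundle(spec)
  cfg <- train_config(num_classes = 2, max_iterations = 200,
                      supervised_only = TRUE, val_interval = 0)
  fit <- train(cfg, b$labeled, b$unlabeled,
               list(images = b$test$images, masks = b$test$masks))
  it <- fit$log$iterations
  expect_lt(mean(tail(it$total, 10)), it$total[1])
  expect_gt(tail(fit$log$validation$miou, 1), 0.5)
})

test_that("losses stay finite over random batches", {
  set.seed(41)
  cfg <- train_config(num_classes = 3, max_iterations = 40, alpha = 0.8)
  state <- init_train_state(cfg)
  for (i in 1:40) {
    K <- 3
    img_l <- matrix(runif(100), 10, 10)
    img_u <- matrix(runif(100), 10, 10)
    batch <- list(Xl = pixel_features(img_l),
                  yl = sample(0:2, 100, replace = TRUE),
                  Xu = pixel_features(img_u))
    res <- run_iteration(state, batch, cfg)
    state <- res$state
    L <- res$artifacts$losses
    expect_true(is.finite(L$supervised))
    expect_true(is.finite(L$unsupervised))
    expect_true(is.finite(L$total))
  }
})

test_that("checkpoint resume reproduces an uninterrupted run bit for bit", {
  b <- tiny_bundle()
  cfg <- train_config(max_iterations = 20, val_interval = 0)
  full <- train(cfg, b$labeled, b$unlabeled)

  cfg10 <- cfg; cfg10$max_iterations <- 10L
  half <- train(cfg10, b$labeled, b$unlabeled)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_checkpoint(half$state, cfg, path)
  ck <- load_checkpoint(path, restore_rng = TRUE)
  resumed <- train(ck$config, b$labeled, b$unlabeled, state = ck$state,
                   reseed = FALSE)
  expect_equal(resumed$model1$params, full$model1$params,
               tolerance = 1e-12)
  expect_equal(resumed$log$iterations$total,
               full$log$iterations$total[11:20], tolerance = 1e-12)
})

test_that("engine validates its inputs", {
  b <- tiny_bundle()
  cfg <- train_config(max_iterations = 5)
  expect_error(train(cfg, list(images = list(), masks = list()),
                     b$unlabeled), "empty")
  bad_masks <- lapply(b$labeled$masks, function(m) m + 10L)
  expect_error(train(cfg, list(images = b$labeled$images,
                               masks = bad_masks), b$unlabeled),
               "disagree on K")
  expect_error(train(cfg, b$labeled, NULL), "unlabeled")
  # supervised_only forces the other switches off
  cfg_sup <- train_config(supervised_only = TRUE)
  expect_false(cfg_sup$use_alignment)
  expect_false(cfg_sup$use_oe)
})
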