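#' Co-training engine
#'
#' One training iteration follows the co-distribution-alignment procedure:
#' each of the two networks predicts on the labeled and unlabeled
#' sub-batches; each network's labeled distribution matrix is updated from
#' its labeled predictions and its unlabeled matrix from its pseudo-classes
#' on the unlabeled batch; the unlabeled predictions are passed through the
#' class-wise coefficient transformation; pseudo-labels with
#' over-expectation filtering are exchanged between the networks; and both
#' networks take an SGD step on the supervised loss plus the (weighted)
#' unsupervised loss. Distribution matrices are running statistics — they
#' never receive gradients.
#'
#' @name cotrain-engine
NULL

#' Training configuration
#'
#' @param num_classes K.
#' @param alpha EMA momentum for the distribution matrices.
#' @param epsilon numerical guard for divisions and powers.
#' @param tau_min lower clamp of the adaptive temperature.
#' @param lambda_u weight of the unsupervised loss in the total
#'   (`total = Ls + lambda_u * Lu`); 1 by default so the two terms are
#'   simply summed.
#' @param learning_rate SGD learning rate.
#' @param sgd_momentum SGD momentum (0.9 by default).
#' @param lr_poly_power polynomial learning-rate decay exponent; 0 (the
#'   default) keeps the rate constant, `p > 0` multiplies it by
#'   `(1 - iter/max_iterations)^p`.
#' @param max_iterations iteration budget.
#' @param batch_labeled,batch_unlabeled images per sub-batch.
#' @param seed1,seed2 parameter seeds of the two networks (must differ).
#' @param data_seed seed of the batch-sampling stream.
#' @param hidden_units backbone hidden width.
#' @param use_alignment apply the coefficient transformation before
#'   pseudo-labeling (off: raw argmax pseudo-labels).
#' @param use_oe apply the over-expectation filter (off: all thresholds 0,
#'   i.e. plain cross-pseudo supervision).
#' @param supervised_only train on the labeled loss alone; forces
#'   `use_alignment` and `use_oe` off.
#' @param static_threshold optional scalar threshold replacing the dynamic
#'   per-class thresholds (for threshold ablations).
#' @param val_interval iterations between validation passes (0 = only at
#'   the end).
#' @return a `train_config` list.
#' @export
train_config <- function(num_classes = 4, alpha = 0.99, epsilon = 1e-8,
                         tau_min = 0.05, lambda_u = 1,
                         learning_rate = 0.5, sgd_momentum = 0.9,
                         lr_poly_power = 0,
                         max_iterations = 500L,
                         batch_labeled = 2L, batch_unlabeled = 4L,
                         seed1 = 1L, seed2 = 2L, data_seed = 100L,
                         hidden_units = 12L,
                         use_alignment = TRUE, use_oe = TRUE,
                         supervised_only = FALSE,
                         static_threshold = NULL,
                         val_interval = 100L) {
  stopifnot(num_classes >= 2, alpha >= 0, alpha <= 1, epsilon > 0,
            tau_min > 0, tau_min <= 1, lambda_u >= 0, learning_rate > 0,
            sgd_momentum >= 0, sgd_momentum < 1, lr_poly_power >= 0,
            max_iterations >= 1, batch_labeled >= 1, batch_unlabeled >= 1,
            val_interval >= 0)
  if (supervised_only) {
    use_alignment <- FALSE
    use_oe <- FALSE
  }
  structure(list(num_classes = as.integer(num_classes), alpha = alpha,
                 epsilon = epsilon, tau_min = tau_min, lambda_u = lambda_u,
                 learning_rate = learning_rate, sgd_momentum = sgd_momentum,
                 lr_poly_power = lr_poly_power,
                 max_iterations = as.integer(max_iterations),
                 batch_labeled = as.integer(batch_labeled),
                 batch_unlabeled = as.integer(batch_unlabeled),
                 seed1 = as.integer(seed1), seed2 = as.integer(seed2),
                 data_seed = as.integer(data_seed),
                 hidden_units = as.integer(hidden_units),
                 use_alignment = isTRUE(use_alignment),
                 use_oe = isTRUE(use_oe),
                 supervised_only = isTRUE(supervised_only),
                 static_threshold = static_threshold,
                 val_interval = as.integer(val_interval)),
            class = "train_config")
}

ema_from_config <- function(config) {
  ema_config(alpha = config$alpha, epsilon = config$epsilon,
             tau_min = config$tau_min)
}

# Prepare a dataset part: stack pixel features and labels per image.
prep_images <- function(images) lapply(images, pixel_features)

#' One co-training iteration (pure)
#'
#' Advances the training state by one iteration on explicit sub-batches.
#' Exposed mainly so that the effect of the ablation switches can be
#' observed on identical inputs: with the same state and batch, toggling
#' `use_alignment` changes only the aligned maps and the pseudo-labels /
#' confidences derived from them, and toggling `use_oe` changes only the
#' acceptance masks.
#'
#' @param state list with `model1`, `model2`, `Ml1`, `Mu1`, `Ml2`, `Mu2`,
#'   `iter` (see [init_train_state()]).
#' @param batch list with `Xl` (labeled feature matrix), `yl` (0-based
#'   labels) and `Xu` (unlabeled feature matrix).
#' @param config a [train_config()].
#' @return list with the updated `state` and an `artifacts` list holding
#'   every intermediate: raw and aligned probability maps, both models'
#'   updated matrices, exchanged pseudo-labels, and a `losses` record
#'   (`supervised`, `unsupervised`, `total`, `accepted_fraction1/2`).
#' @export
run_iteration <- function(state, batch, config) {
  cfg <- ema_from_config(config)
  K <- config$num_classes
  f1l <- model_forward(state$model1, batch$Xl)
  f2l <- model_forward(state$model2, batch$Xl)
  p1l <- prob_map(f1l$probs); p2l <- prob_map(f2l$probs)
  Ls <- supervised_loss(p1l, p2l, batch$yl)

  nl <- nrow(batch$Xl)
  onehot_l <- matrix(0, nl, K)
  onehot_l[cbind(seq_len(nl), batch$yl + 1L)] <- 1
  # d(Ls)/dZ for each model: its own softmax CE term, mean over pixels
  g1 <- model_backward(state$model1, batch$Xl, f1l,
                       (f1l$probs - onehot_l) / nl)
  g2 <- model_backward(state$model2, batch$Xl, f2l,
                       (f2l$probs - onehot_l) / nl)

  artifacts <- list(raw_labeled1 = p1l, raw_labeled2 = p2l)
  Lu <- 0; af1 <- NA_real_; af2 <- NA_real_

  if (!config$supervised_only) {
    f1u <- model_forward(state$model1, batch$Xu)
    f2u <- model_forward(state$model2, batch$Xu)
    p1u <- prob_map(f1u$probs); p2u <- prob_map(f2u$probs)
    artifacts$raw_unlabeled1 <- p1u
    artifacts$raw_unlabeled2 <- p2u

    state$Ml1 <- update_labeled_distribution(state$Ml1, p1l, batch$yl, cfg)
    state$Ml2 <- update_labeled_distribution(state$Ml2, p2l, batch$yl, cfg)
    state$Mu1 <- update_unlabeled_distribution(state$Mu1, state$Ml1, p1u,
                                               cfg)
    state$Mu2 <- update_unlabeled_distribution(state$Mu2, state$Ml2, p2u,
                                               cfg)

    if (config$use_alignment) {
      # per-class log-weights shift the logits, so the aligned softmax and
      # its gradient come for free
      W1 <- alignment_weights(state$Ml1, state$Mu1, cfg)
      W2 <- alignment_weights(state$Ml2, state$Mu2, cfg)
      cls1 <- max.col(f1u$probs, ties.method = "first")
      cls2 <- max.col(f2u$probs, ties.method = "first")
      Za1 <- f1u$logits + log(W1)[cls1, , drop = FALSE]
      Za2 <- f2u$logits + log(W2)[cls2, , drop = FALSE]
      a1 <- prob_map(softmax_rows(Za1), aligned = TRUE)
      a2 <- prob_map(softmax_rows(Za2), aligned = TRUE)
    } else {
      a1 <- prob_map(f1u$probs, aligned = TRUE)
      a2 <- prob_map(f2u$probs, aligned = TRUE)
    }
    artifacts$aligned1 <- a1
    artifacts$aligned2 <- a2

    thr <- if (!config$use_oe) 0 else config$static_threshold
    pl1 <- build_pseudo_labels(a1, state$Mu1, static_threshold = thr,
                               source = "model1")
    pl2 <- build_pseudo_labels(a2, state$Mu2, static_threshold = thr,
                               source = "model2")
    artifacts$pseudo1 <- pl1
    artifacts$pseudo2 <- pl2
    af1 <- mean(pl1$accept_mask)
    af2 <- mean(pl2$accept_mask)

    # each model is supervised by the other's pseudo-labels on its own
    # (aligned, when alignment is on) prediction
    self1 <- a1; self2 <- a2
    Lu <- oe_loss(self1, pl2) + oe_loss(self2, pl1)

    nu <- nrow(batch$Xu)
    dZ_dir <- function(self_probs, pl) {
      D <- self_probs$values
      Y <- matrix(0, nu, K)
      Y[cbind(seq_len(nu), pl$labels + 1L)] <- 1
      (D - Y) * (pl$accept_mask / nu)
    }
    gu1 <- model_backward(state$model1, batch$Xu, f1u,
                          config$lambda_u * dZ_dir(self1, pl2))
    gu2 <- model_backward(state$model2, batch$Xu, f2u,
                          config$lambda_u * dZ_dir(self2, pl1))
    g1 <- Map(`+`, g1, gu1)
    g2 <- Map(`+`, g2, gu2)
  }

  lr <- config$learning_rate
  if (config$lr_poly_power > 0)
    lr <- lr * (1 - (state$iter) / config$max_iterations)^
      config$lr_poly_power
  state$model1 <- model_step(state$model1, g1, lr, config$sgd_momentum)
  state$model2 <- model_step(state$model2, g2, lr, config$sgd_momentum)
  state$iter <- state$iter + 1L

  artifacts$losses <- list(
    supervised = Ls, unsupervised = Lu,
    total = Ls + config$lambda_u * Lu,
    accepted_fraction1 = af1, accepted_fraction2 = af2)
  list(state = state, artifacts = artifacts)
}

#' Initialize the training state
#'
#' @param config a [train_config()].
#' @return list with the two models, their (Ml, Mu) matrix pairs and the
#'   iteration counter at 0.
#' @export
init_train_state <- function(config) {
  models <- make_model_pair(config)
  K <- config$num_classes
  list(model1 = models[[1]], model2 = models[[2]],
       Ml1 = init_distributions(K, "labeled"),
       Mu1 = init_distributions(K, "unlabeled"),
       Ml2 = init_distributions(K, "labeled"),
       Mu2 = init_distributions(K, "unlabeled"),
       iter = 0L)
}

sample_batch_indices <- function(n, size) {
  if (size >= n) c(seq_len(n), sample.int(n, size - n, replace = TRUE))
  else sample.int(n, size)
}

validate_models <- function(state, val_images, val_masks, K) {
  preds <- lapply(seq_along(val_images), function(i) {
    X <- val_images[[i]]
    P <- (model_forward(state$model1, X)$probs +
            model_forward(state$model2, X)$probs) / 2
    max.col(P, ties.method = "first") - 1L
  })
  counts <- confusion_counts(unlist(preds),
                             unlist(lapply(val_masks, as.integer)), K)
  list(miou = miou(counts), class_iou = class_iou(counts))
}

#' Train a co-distribution-aligned model pair
#'
#' Runs the full training loop: two differently seeded networks,
#' per-iteration distribution updates, aligned pseudo-label exchange with
#' over-expectation filtering, and SGD on `Ls + lambda_u * Lu`. The run is
#' a pure function of the configuration and data: identical inputs give
#' bit-identical logs.
#'
#' @param config a [train_config()].
#' @param labeled_data list with `images` (H x W matrices) and `masks`
#'   (integer matrices in `{0..K-1}`).
#' @param unlabeled_data list with `images`; may be empty only when
#'   `supervised_only` is set.
#' @param validation_data optional list with `images` and `masks` for
#'   periodic mIoU evaluation.
#' @param state optional training state to resume from (e.g. from
#'   [load_checkpoint()]); when given, iterations continue from
#'   `state$iter + 1` and the sampling stream is NOT reseeded unless
#'   `reseed` is `TRUE`.
#' @param reseed reseed the batch-sampling stream from `config$data_seed`
#'   (default `TRUE` for fresh runs, set `FALSE` when resuming with a
#'   restored RNG state).
#' @return list with `model1`, `model2`, the final `state`, and `log` — a
#'   `train_log` with one record per iteration (losses, accepted
#'   fractions, the diagonals of all four distribution matrices) and a
#'   `validation` table.
#' @export
train <- function(config, labeled_data, unlabeled_data = NULL,
                  validation_data = NULL, state = NULL, reseed = TRUE) {
  stopifnot(inherits(config, "train_config"))
  K <- config$num_classes
  if (length(labeled_data$images) == 0L)
    stop("labeled dataset is empty", call. = FALSE)
  lab_classes <- unique(unlist(lapply(labeled_data$masks,
                                      function(m) unique(as.integer(m)))))
  if (any(lab_classes < 0L) || any(lab_classes >= K))
    stop("labeled masks contain classes outside {0..", K - 1L,
         "}; config and masks disagree on K", call. = FALSE)
  has_unlab <- !is.null(unlabeled_data) &&
    length(unlabeled_data$images) > 0L
  if (!config$supervised_only && !has_unlab)
    stop("unlabeled dataset is empty; use supervised_only for a purely ",
         "supervised run", call. = FALSE)

  Xl_all <- prep_images(labeled_data$images)
  yl_all <- lapply(labeled_data$masks, function(m) as.integer(m))
  Xu_all <- if (has_unlab) prep_images(unlabeled_data$images) else list()
  Xv_all <- if (!is.null(validation_data))
    prep_images(validation_data$images) else NULL

  if (is.null(state)) state <- init_train_state(config)
  if (reseed) set.seed(config$data_seed)

  n_iter <- config$max_iterations - state$iter
  records <- vector("list", n_iter)
  validations <- list()
  for (step in seq_len(n_iter)) {
    li <- sample_batch_indices(length(Xl_all), config$batch_labeled)
    batch <- list(Xl = do.call(rbind, Xl_all[li]),
                  yl = unlist(yl_all[li]))
    if (!config$supervised_only) {
      ui <- sample_batch_indices(length(Xu_all), config$batch_unlabeled)
      batch$Xu <- do.call(rbind, Xu_all[ui])
    }
    res <- run_iteration(state, batch, config)
    state <- res$state
    L <- res$artifacts$losses
    records[[step]] <- data.frame(
      iteration = state$iter,
      supervised = L$supervised, unsupervised = L$unsupervised,
      total = L$total,
      accepted_fraction1 = L$accepted_fraction1,
      accepted_fraction2 = L$accepted_fraction2,
      diag_Ml1 = I(list(diag(state$Ml1$entries))),
      diag_Mu1 = I(list(diag(state$Mu1$entries))),
      diag_Ml2 = I(list(diag(state$Ml2$entries))),
      diag_Mu2 = I(list(diag(state$Mu2$entries))))
    at_end <- state$iter == config$max_iterations
    if (!is.null(Xv_all) &&
        (at_end || (config$val_interval > 0L &&
                    state$iter %% config$val_interval == 0L))) {
      v <- validate_models(state, Xv_all, validation_data$masks, K)
      validations[[length(validations) + 1L]] <-
        c(list(iteration = state$iter, miou = v$miou),
          stats::setNames(as.list(v$class_iou),
                          paste0("iou_class", seq_along(v$class_iou) - 1L)))
    }
  }
  log <- structure(
    list(iterations = do.call(rbind, records),
         validation = if (length(validations))
           do.call(rbind, lapply(validations, as.data.frame))
         else NULL),
    class = "train_log")
  list(model1 = state$model1, model2 = state$model2, state = state,
       log = log)
}

#' @export
print.train_log <- function(x, ...) {
  n <- nrow(x$iterations)
  cat(sprintf("<train_log: %d iterations>\n", n))
  if (n > 0)
    cat(sprintf("  final losses: Ls = %.4f, Lu = %.4f\n",
                x$iterations$supervised[n], x$iterations$unsupervised[n]))
  if (!is.null(x$validation)) {
    v <- x$validation
    cat(sprintf("  final validation mIoU = %.4f (iteration %d)\n",
                v$miou[nrow(v)], v$iteration[nrow(v)]))
  }
  invisible(x)
}

#' Write a training log as JSON-lines
#'
#' One JSON object per iteration; validation records carry a
#' `"type": "validation"` field.
#'
#' @param log a `train_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(log, path) {
  stopifnot(inherits(log, "train_log"))
  con <- file(path, "w")
  on.exit(close(con))
  it <- log$iterations
  for (i in seq_len(nrow(it))) {
    rec <- list(type = "iteration", iteration = it$iteration[i],
                supervised = it$supervised[i],
                unsupervised = it$unsupervised[i], total = it$total[i],
                accepted_fraction1 = it$accepted_fraction1[i],
                accepted_fraction2 = it$accepted_fraction2[i],
                diag_Ml1 = it$diag_Ml1[[i]], diag_Mu1 = it$diag_Mu1[[i]],
                diag_Ml2 = it$diag_Ml2[[i]], diag_Mu2 = it$diag_Mu2[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  if (!is.null(log$validation)) {
    v <- log$validation
    for (i in seq_len(nrow(v))) {
      rec <- c(list(type = "validation"), as.list(v[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' Save / load a training checkpoint
#'
#' The checkpoint holds both models' parameters and optimizer velocities,
#' both (Ml, Mu) pairs, the iteration counter, the resolved configuration
#' and the RNG state of the sampling stream, so a resumed deterministic run
#' reproduces an uninterrupted one bit for bit.
#'
#' @param state a training state (see [init_train_state()]).
#' @param config the [train_config()] of the run.
#' @param path checkpoint file (JSON).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `state`, `config` and restores nothing globally
#'   except when `restore_rng = TRUE`, in which case the saved sampling RNG
#'   state is reinstated.
#' @export
save_checkpoint <- function(state, config, path) {
  doc <- list(
    iter = state$iter,
    model1 = model_to_list(state$model1),
    model2 = model_to_list(state$model2),
    Ml1 = list(entries = state$Ml1$entries),
    Mu1 = list(entries = state$Mu1$entries),
    Ml2 = list(entries = state$Ml2$entries),
    Mu2 = list(entries = state$Mu2$entries),
    config = unclass(config),
    rng_state = if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param restore_rng reinstate the checkpointed RNG state (needed for
#'   bit-compatible resumption).
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(e) {
    if (is.list(e)) e <- do.call(rbind, e)
    matrix(as.numeric(e), nrow = NROW(e))
  }
  cfg_args <- doc$config
  cfg_args$static_threshold <- doc$config$static_threshold
  config <- do.call(train_config, cfg_args[names(cfg_args) %in%
                                             names(formals(train_config))])
  state <- list(
    model1 = model_from_list(doc$model1),
    model2 = model_from_list(doc$model2),
    Ml1 = new_class_dist(as_mat(doc$Ml1$entries), "labeled"),
    Mu1 = new_class_dist(as_mat(doc$Mu1$entries), "unlabeled"),
    Ml2 = new_class_dist(as_mat(doc$Ml2$entries), "labeled"),
    Mu2 = new_class_dist(as_mat(doc$Mu2$entries), "unlabeled"),
    iter = as.integer(doc$iter))
  if (restore_rng && !is.null(doc$rng_state))
    assign(".Random.seed", as.integer(doc$rng_state), globalenv())
  list(state = state, config = config)
}
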