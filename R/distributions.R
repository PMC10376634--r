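#' Class-wise marginal prediction distributions
#'
#' The alignment machinery keeps, per model, two K x K matrices: a labeled
#' matrix `Ml` and an unlabeled matrix `Mu`. Row `i` of each matrix is the
#' exponential-moving-average estimate of the network's mean predicted
#' probability vector over pixels whose (true, for `Ml`; pseudo, for `Mu`)
#' class is `i` — a class-conditional marginal prediction distribution, so
#' each row lives on the probability simplex. Unlabeled predictions are then
#' rescaled row-wise by the ratio of the two distributions, which pulls the
#' class statistics on unlabeled data toward those observed on labeled data
#' and counteracts the majority-class bias of pseudo-labels on imbalanced
#' tasks.
#'
#' @name class-distributions
NULL

#' EMA and numerical-guard configuration
#'
#' @param alpha EMA momentum in `[0, 1]`; the estimate averages roughly the
#'   last `1/(1 - alpha)` iterations. Default 0.99 (~100 iterations).
#' @param epsilon small positive guard added to divisors, and used as the
#'   base of entrywise powers when an entry is 0.
#' @param tau_min lower clamp for the adaptive temperature, in `(0, 1]`.
#'   A temperature approaching 0 together with a zero entry in a labeled row
#'   is ill-conditioned, hence the clamp.
#' @return a list of class `ema_config`.
#' @export
ema_config <- function(alpha = 0.99, epsilon = 1e-8, tau_min = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(tau_min), length(tau_min) == 1L,
            tau_min > 0, tau_min <= 1)
  structure(list(alpha = alpha, epsilon = epsilon, tau_min = tau_min),
            class = "ema_config")
}

new_class_dist <- function(entries, role) {
  structure(list(entries = entries, num_classes = ncol(entries), role = role),
            class = "class_dist")
}

#' Initialize a class-wise distribution matrix
#'
#' Rows start uniform (`1/K` everywhere), which makes the coefficient
#' transformation an exact identity at step 0 and so introduces no bias
#' before any statistics have been observed.
#'
#' @param num_classes number of classes K, at least 2.
#' @param role `"labeled"` or `"unlabeled"`.
#' @return a `class_dist` object with a K x K `entries` matrix.
#' @export
init_distributions <- function(num_classes, role = c("labeled", "unlabeled")) {
  role <- match.arg(role)
  if (!is.numeric(num_classes) || length(num_classes) != 1L ||
      num_classes != round(num_classes) || num_classes < 2)
    stop("`num_classes` must be an integer >= 2", call. = FALSE)
  K <- as.integer(num_classes)
  new_class_dist(matrix(1 / K, K, K), role)
}

#' @export
print.class_dist <- function(x, ...) {
  cat(sprintf("<class_dist: %s, K = %d>\n", x$role, x$num_classes))
  print(round(x$entries, 4))
  invisible(x)
}

check_class_dist <- function(M, role = NULL, arg = "M") {
  if (!inherits(M, "class_dist"))
    stop("`", arg, "` must be a class_dist object", call. = FALSE)
  if (!is.null(role) && M$role != role)
    stop("`", arg, "` must have role \"", role, "\", got \"", M$role, "\"",
         call. = FALSE)
  invisible(M)
}

#' Check the simplex invariant of a distribution matrix
#'
#' @param M a `class_dist`.
#' @param tol tolerance on each row sum.
#' @return `TRUE` invisibly; errors if violated.
#' @export
validate_distribution <- function(M, tol = 1e-6) {
  check_class_dist(M)
  if (any(M$entries < 0) || any(M$entries > 1))
    stop("distribution entries must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(M$entries)
  if (any(abs(rs - 1) > tol))
    stop("distribution rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  invisible(TRUE)
}

# Conditional mean probability vector per class over a pixel batch.
# Returns list(means = K x K matrix (row i = mean vector of class-i pixels,
# NA rows for absent classes), present = logical K-vector).
class_conditional_means <- function(values, labels, K) {
  means <- matrix(NA_real_, K, K)
  present <- logical(K)
  for (i in seq_len(K) - 1L) {
    idx <- which(labels == i)
    if (length(idx) > 0L) {
      present[i + 1L] <- TRUE
      means[i + 1L, ] <- colMeans(values[idx, , drop = FALSE])
    }
  }
  list(means = means, present = present)
}

#' EMA update of the labeled distribution matrix
#'
#' For each class `i` present in the batch, row `i` becomes
#' `alpha * row_i + (1 - alpha) * m_i`, where `m_i` is the mean predicted
#' probability vector over the batch pixels whose ground-truth label is `i`
#' (the class-conditional batch mean, so the row stays on the simplex).
#' Rows of classes absent from the batch are left unchanged. The input
#' matrix is not mutated.
#'
#' @param M labeled `class_dist`.
#' @param probs raw (unaligned) `prob_map` for the labeled batch.
#' @param labels integer vector of ground-truth classes in `{0..K-1}`, one
#'   per pixel of `probs`.
#' @param cfg an [ema_config()].
#' @return the updated labeled `class_dist`.
#' @export
update_labeled_distribution <- function(M, probs, labels,
                                        cfg = ema_config()) {
  check_class_dist(M, role = "labeled")
  check_prob_map(probs, K = M$num_classes)
  if (probs$aligned)
    stop("distribution updates must consume raw (unaligned) predictions",
         call. = FALSE)
  K <- M$num_classes
  labels <- check_labels(labels, K, nrow(probs$values))
  cm <- class_conditional_means(probs$values, labels, K)
  E <- M$entries
  a <- cfg$alpha
  for (i in which(cm$present))
    E[i, ] <- a * E[i, ] + (1 - a) * cm$means[i, ]
  new_class_dist(E, "labeled")
}

# Entrywise mean over the K rows of the ratio matrix Mu_prev / (Ml + eps):
# the average labeled-to-unlabeled transformation, used to synthesize rows
# for classes whose pseudo-labels are absent from a batch.
mean_ratio_vector <- function(Mu_entries, Ml_entries, epsilon) {
  colMeans(Mu_entries / (Ml_entries + epsilon))
}

#' EMA update of the unlabeled distribution matrix
#'
#' Pixels are grouped by their pseudo-class (argmax of the raw prediction).
#' Classes with at least one pseudo-labeled pixel get the same EMA update as
#' the labeled matrix, grouped by pseudo-class. A class absent from the
#' batch — typically a minority class — cannot be updated from data, so its
#' row is synthesized by the inverse transformation: the class's labeled
#' row is multiplied entrywise by the average labeled-to-unlabeled ratio
#' vector (the entrywise mean over all K rows of `Mu_prev / (Ml + epsilon)`)
#' and renormalized.
#'
#' @param Mu unlabeled `class_dist` (previous iteration).
#' @param Ml labeled `class_dist` with the same K.
#' @param probs raw (unaligned) `prob_map` for the unlabeled batch.
#' @param cfg an [ema_config()].
#' @return the updated unlabeled `class_dist`.
#' @export
update_unlabeled_distribution <- function(Mu, Ml, probs,
                                          cfg = ema_config()) {
  check_class_dist(Mu, role = "unlabeled", arg = "Mu")
  check_class_dist(Ml, role = "labeled", arg = "Ml")
  if (Mu$num_classes != Ml$num_classes)
    stop("Ml and Mu disagree on the number of classes (",
         Ml$num_classes, " vs ", Mu$num_classes, ")", call. = FALSE)
  check_prob_map(probs, K = Mu$num_classes)
  if (probs$aligned)
    stop("distribution updates must consume raw (unaligned) predictions",
         call. = FALSE)
  K <- Mu$num_classes
  pseudo <- max.col(probs$values, ties.method = "first") - 1L
  cm <- class_conditional_means(probs$values, pseudo, K)
  E <- Mu$entries
  a <- cfg$alpha
  ratio <- mean_ratio_vector(Mu$entries, Ml$entries, cfg$epsilon)
  for (i in seq_len(K)) {
    if (cm$present[i]) {
      E[i, ] <- a * E[i, ] + (1 - a) * cm$means[i, ]
    } else {
      v <- Ml$entries[i, ] * ratio
      E[i, ] <- v / sum(v)
    }
  }
  new_class_dist(E, "unlabeled")
}

#' Adaptive per-class temperature
#'
#' The temperature of class `i` is `1 - Ml[i, i]`, clamped to
#' `[tau_min, 1]`: the better the network already recognizes class `i` on
#' labeled data (large diagonal entry), the smaller the temperature, i.e.
#' the flatter the labeled row used in the coefficient transformation and
#' the smaller the shift it induces. For poorly learned (typically
#' minority) classes the temperature stays near 1 and the full labeled row
#' is applied.
#'
#' @param Ml labeled `class_dist`.
#' @param class_index 0-based class index.
#' @param cfg an [ema_config()] (supplies `tau_min`).
#' @return a scalar temperature in `(0, 1]`.
#' @export
compute_temperature <- function(Ml, class_index, cfg = ema_config()) {
  check_class_dist(Ml, arg = "Ml")
  K <- Ml$num_classes
  if (!is.numeric(class_index) || length(class_index) != 1L ||
      class_index != round(class_index) ||
      class_index < 0 || class_index >= K)
    stop("`class_index` must be an integer in {0..", K - 1L, "}",
         call. = FALSE)
  tau <- 1 - Ml$entries[class_index + 1L, class_index + 1L]
  min(max(tau, cfg$tau_min), 1)
}

#' Class-wise coefficient transformation of unlabeled predictions
#'
#' For each pixel, let `i` be its most probable class under the raw
#' prediction. The pixel's probability vector is multiplied entrywise by
#' `Ml[i, ]^tau_i / (Mu[i, ] + epsilon)` (the temperature `tau_i` from
#' [compute_temperature()], the power taken entrywise with zero entries
#' guarded by `epsilon`) and renormalized to sum to 1. With both matrices
#' uniform the weight vector is constant and the transformation is the
#' identity.
#'
#' @param probs raw (unaligned) `prob_map`.
#' @param Ml,Mu labeled and unlabeled `class_dist` with matching K.
#' @param cfg an [ema_config()].
#' @return an aligned `prob_map` of the same shape.
#' @export
align_prediction <- function(probs, Ml, Mu, cfg = ema_config()) {
  check_prob_map(probs)
  if (probs$aligned)
    stop("`probs` is already aligned; alignment applies to raw output",
         call. = FALSE)
  check_class_dist(Ml, role = "labeled", arg = "Ml")
  check_class_dist(Mu, role = "unlabeled", arg = "Mu")
  K <- probs$num_classes
  if (Ml$num_classes != K || Mu$num_classes != K)
    stop("probability map and distribution matrices disagree on K",
         call. = FALSE)
  W <- alignment_weights(Ml, Mu, cfg)
  pseudo <- max.col(probs$values, ties.method = "first")
  V <- probs$values * W[pseudo, , drop = FALSE]
  V <- V / rowSums(V)
  prob_map(V, aligned = TRUE)
}

# K x K matrix of per-class alignment weight vectors:
# row i = (Ml_row_i guarded by eps)^tau_i / (Mu_row_i + eps).
alignment_weights <- function(Ml, Mu, cfg) {
  K <- Ml$num_classes
  W <- matrix(0, K, K)
  for (i in seq_len(K)) {
    tau <- compute_temperature(Ml, i - 1L, cfg)
    W[i, ] <- pmax(Ml$entries[i, ], cfg$epsilon)^tau /
      (Mu$entries[i, ] + cfg$epsilon)
  }
  W
}

#' Serialize / deserialize a distribution matrix as JSON
#'
#' The JSON document is `{"num_classes": K, "role": "...",
#' "entries": [[...], ...]}`; the round trip is lossless to full double
#' precision.
#'
#' @param M a `class_dist`.
#' @param path file path.
#' @return `write_distribution` returns `path` invisibly;
#'   `read_distribution` returns a `class_dist`.
#' @export
write_distribution <- function(M, path) {
  check_class_dist(M)
  doc <- list(num_classes = M$num_classes, role = M$role,
              entries = M$entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- doc$entries
  if (is.list(entries)) entries <- do.call(rbind, entries)
  entries <- matrix(as.numeric(entries), nrow = as.integer(doc$num_classes))
  M <- new_class_dist(entries, doc$role)
  validate_distribution(M)
  M
}
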