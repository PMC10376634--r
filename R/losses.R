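#' Losses for co-training with pseudo-label filtering
#'
#' Three losses drive training: a supervised cross-entropy on labeled
#' pixels summed over both networks; the cross-pseudo-supervision (CPS)
#' loss, in which each network's hard pseudo-labels supervise the other
#' network's prediction on unlabeled pixels; and the over-expectation (O-E)
#' cross-entropy, a CPS variant that keeps only pixels whose pseudo-label
#' confidence strictly exceeds a dynamic per-class threshold — the class's
#' own expected confidence, read off the diagonal of the unlabeled
#' distribution matrix.
#'
#' @name coda-losses
NULL

# floor inside log() so that a (numerically) zero probability yields a large
# finite loss rather than Inf
LOG_GUARD <- 1e-12

#' Supervised cross-entropy over both networks
#'
#' Mean over labeled pixels of `-(log p1[y] + log p2[y])`, where `p1`, `p2`
#' are the two networks' predicted probabilities of the true class `y`.
#' Zero exactly when both networks put probability 1 on the true class at
#' every pixel; symmetric in the two maps.
#'
#' @param probs1,probs2 `prob_map`s from the two networks on the same
#'   labeled batch.
#' @param labels ground-truth classes in `{0..K-1}`, one per pixel.
#' @return a nonnegative scalar.
#' @export
supervised_loss <- function(probs1, probs2, labels) {
  check_prob_map(probs1, arg = "probs1")
  check_prob_map(probs2, K = probs1$num_classes, arg = "probs2")
  n <- nrow(probs1$values)
  if (nrow(probs2$values) != n)
    stop("probs1 and probs2 have different pixel counts", call. = FALSE)
  labels <- check_labels(labels, probs1$num_classes, n)
  idx <- cbind(seq_len(n), labels + 1L)
  p1 <- pmax(probs1$values[idx], LOG_GUARD)
  p2 <- pmax(probs2$values[idx], LOG_GUARD)
  -mean(log(p1) + log(p2))
}

#' Dynamic pseudo-label threshold for one class
#'
#' The threshold of class `i` is the diagonal entry `Mu[i, i]` of the
#' unlabeled distribution matrix: the running estimate of the confidence
#' the network typically assigns to class `i` on unlabeled pixels it
#' pseudo-labels as `i`. A pseudo-label is kept only if its confidence is
#' strictly above this expectation.
#'
#' @param Mu unlabeled `class_dist`.
#' @param class_index 0-based class index.
#' @return a threshold in `[0, 1]`.
#' @export
compute_oe_threshold <- function(Mu, class_index) {
  check_class_dist(Mu, arg = "Mu")
  K <- Mu$num_classes
  if (!is.numeric(class_index) || length(class_index) != 1L ||
      class_index != round(class_index) ||
      class_index < 0 || class_index >= K)
    stop("`class_index` must be an integer in {0..", K - 1L, "}",
         call. = FALSE)
  Mu$entries[class_index + 1L, class_index + 1L]
}

#' Build a pseudo-label map from an aligned prediction
#'
#' Labels are the per-pixel argmax, confidences the per-pixel maximum of
#' the aligned probabilities. The acceptance mask applies the
#' over-expectation filter: a pixel is accepted iff its confidence is
#' strictly greater than the threshold of its pseudo-class — by default the
#' dynamic threshold of [compute_oe_threshold()] under the generating
#' model's own `Mu`, or a single static scalar if `static_threshold` is
#' given (provided for threshold-ablation comparisons).
#'
#' @param aligned an aligned `prob_map` (raw maps are refused: pseudo-labels
#'   always come from aligned output).
#' @param Mu the generating model's unlabeled `class_dist`.
#' @param static_threshold optional scalar in `[0, 1]` overriding the
#'   per-class dynamic thresholds.
#' @param source identifier of the generating model, kept for bookkeeping.
#' @return a `pseudo_labels` object with fields `labels` (0-based),
#'   `confidences`, `accept_mask`, `thresholds` (per class) and `source`.
#' @export
build_pseudo_labels <- function(aligned, Mu, static_threshold = NULL,
                                source = "model") {
  check_prob_map(aligned, arg = "aligned")
  if (!aligned$aligned)
    stop("pseudo-labels must be built from an aligned probability map",
         call. = FALSE)
  check_class_dist(Mu, arg = "Mu")
  K <- aligned$num_classes
  if (Mu$num_classes != K)
    stop("aligned map and Mu disagree on K", call. = FALSE)
  if (!is.null(static_threshold)) {
    stopifnot(is.numeric(static_threshold), length(static_threshold) == 1L,
              static_threshold >= 0, static_threshold <= 1)
    thresholds <- rep(static_threshold, K)
  } else {
    thresholds <- diag(Mu$entries)
  }
  labels <- max.col(aligned$values, ties.method = "first") - 1L
  conf <- aligned$values[cbind(seq_along(labels), labels + 1L)]
  structure(
    list(labels = labels, confidences = conf,
         accept_mask = conf > thresholds[labels + 1L],
         thresholds = thresholds, source = source),
    class = "pseudo_labels"
  )
}

#' @export
print.pseudo_labels <- function(x, ...) {
  cat(sprintf("<pseudo_labels from %s: %d pixels, %.1f%% accepted>\n",
              x$source, length(x$labels), 100 * mean(x$accept_mask)))
  invisible(x)
}

#' Over-expectation cross-entropy (one direction)
#'
#' Mean over ALL unlabeled pixels of
#' `accept * (-log p_self[pseudo-label])`: rejected pixels contribute zero
#' but stay in the denominator, so raising thresholds can only shrink the
#' accept set and weakly decrease the loss. With all thresholds at zero
#' (every confidence strictly positive accepted) this reduces to the plain
#' CPS loss for this direction. The engine sums the two directions to form
#' the unsupervised loss.
#'
#' @param probs_self the supervised model's own `prob_map` on the unlabeled
#'   batch (the differentiated quantity).
#' @param pseudo_other a `pseudo_labels` object built from the OTHER
#'   model's aligned output.
#' @return a nonnegative scalar.
#' @export
oe_loss <- function(probs_self, pseudo_other) {
  check_prob_map(probs_self, arg = "probs_self")
  if (!inherits(pseudo_other, "pseudo_labels"))
    stop("`pseudo_other` must be a pseudo_labels object", call. = FALSE)
  n <- nrow(probs_self$values)
  if (length(pseudo_other$labels) != n)
    stop("probability map and pseudo-label map have mismatched pixel counts",
         call. = FALSE)
  acc <- pseudo_other$accept_mask
  if (!any(acc)) return(0)
  idx <- cbind(which(acc), pseudo_other$labels[acc] + 1L)
  p <- pmax(probs_self$values[idx], LOG_GUARD)
  sum(-log(p)) / n
}

#' Cross-pseudo-supervision loss (one direction, no filtering)
#'
#' Plain CPS: mean over all unlabeled pixels of
#' `-log p_self[argmax of the other model]`. Equivalent to [oe_loss()] with
#' every threshold at zero.
#'
#' @param probs_self the supervised model's own `prob_map`.
#' @param labels_other 0-based hard pseudo-labels from the other model.
#' @return a nonnegative scalar.
#' @export
cps_loss <- function(probs_self, labels_other) {
  check_prob_map(probs_self, arg = "probs_self")
  n <- nrow(probs_self$values)
  labels_other <- check_labels(labels_other, probs_self$num_classes, n)
  p <- pmax(probs_self$values[cbind(seq_len(n), labels_other + 1L)],
            LOG_GUARD)
  -mean(log(p))
}
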