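#' Per-pixel class-probability map
#'
#' A `prob_map` holds the per-pixel class-probability vectors produced by a
#' segmentation network, one row per pixel and one column per class. The
#' `aligned` flag records whether the map is the raw network output or the
#' result of the class-wise coefficient transformation
#' (see [align_prediction()]): pseudo-labels are only ever built from aligned
#' maps, so the flag is part of the contract, not a decoration.
#'
#' @param values numeric matrix, `n_pixels x K`; every row must be a
#'   probability vector (nonnegative, summing to 1 within `1e-6`).
#' @param aligned logical flag; `FALSE` for raw network output.
#' @return an object of class `prob_map`.
#' @export
prob_map <- function(values, aligned = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (pixels x classes)", call. = FALSE)
  if (ncol(values) < 2L)
    stop("a probability map needs at least 2 classes", call. = FALSE)
  if (any(values < -1e-9))
    stop("probability values must be nonnegative", call. = FALSE)
  sums <- rowSums(values)
  if (any(abs(sums - 1) > 1e-6))
    stop("every pixel's probability vector must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  structure(
    list(values = values, aligned = isTRUE(aligned),
         num_classes = ncol(values)),
    class = "prob_map"
  )
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map: %d pixels, %d classes, %s>\n",
              nrow(x$values), x$num_classes,
              if (x$aligned) "aligned" else "raw"))
  invisible(x)
}

is_prob_map <- function(x) inherits(x, "prob_map")

check_prob_map <- function(probs, K = NULL, arg = "probs") {
  if (!is_prob_map(probs))
    stop("`", arg, "` must be a prob_map object", call. = FALSE)
  if (!is.null(K) && probs$num_classes != K)
    stop("`", arg, "` has ", probs$num_classes,
         " classes but ", K, " were expected", call. = FALSE)
  invisible(probs)
}

check_labels <- function(labels, K, n_pixels) {
  labels <- as.integer(labels)
  if (length(labels) != n_pixels)
    stop("labels (", length(labels), ") and probability map (", n_pixels,
         " pixels) have mismatched shapes", call. = FALSE)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= K))
    stop("labels must lie in {0..", K - 1L, "}", call. = FALSE)
  labels
}
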