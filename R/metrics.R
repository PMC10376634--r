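#' Segmentation evaluation metrics
#'
#' Overlap metrics are computed from per-class confusion counts:
#' `IoU = TP / (TP + FP + FN)` (Jaccard), `Dice = 2 TP / (2 TP + FP + FN)`,
#' and mIoU is the mean IoU over classes present in at least one of the two
#' rasters. Surface-distance metrics operate on the sets of boundary
#' elements of binary masks: the average surface distance (ASD) sums the
#' nearest-neighbor distances in both directions and divides by the total
#' number of surface elements; the Hausdorff distance (HD) is the larger of
#' the two directed maxima; the 95th-percentile Hausdorff (95HD) replaces
#' each directed maximum by the 95th percentile of the directed nearest
#' distances, robust to a few boundary outliers.
#'
#' @name segmentation-metrics
NULL

#' Per-class confusion counts
#'
#' @param pred,gt integer label rasters (vectors, matrices or arrays of the
#'   same shape) with classes in `{0..num_classes-1}`.
#' @param num_classes number of classes K.
#' @return a `confusion_counts` object: integer vectors `tp`, `fp`, `fn`
#'   indexed by class (0-based classes in element 1..K) plus `total` pixels.
#' @export
confusion_counts <- function(pred, gt, num_classes) {
  if (length(pred) != length(gt) ||
      !identical(dim(pred), dim(gt)))
    stop("pred and gt have mismatched shapes", call. = FALSE)
  K <- as.integer(num_classes)
  stopifnot(K >= 2L)
  p <- as.integer(pred); g <- as.integer(gt)
  if (any(p < 0L) || any(p >= K) || any(g < 0L) || any(g >= K))
    stop("labels must lie in {0..", K - 1L, "}", call. = FALSE)
  tab <- table(factor(g, levels = 0:(K - 1L)),
               factor(p, levels = 0:(K - 1L)))
  tp <- as.integer(diag(tab))
  fn <- as.integer(rowSums(tab)) - tp   # gt class i, predicted otherwise
  fp <- as.integer(colSums(tab)) - tp   # predicted i, gt otherwise
  structure(list(tp = tp, fp = fp, fn = fn, total = length(p),
                 num_classes = K),
            class = "confusion_counts")
}

check_counts <- function(counts, class_index = NULL) {
  if (!inherits(counts, "confusion_counts"))
    stop("`counts` must be a confusion_counts object", call. = FALSE)
  if (!is.null(class_index)) {
    K <- counts$num_classes
    if (class_index < 0 || class_index >= K)
      stop("`class_index` must lie in {0..", K - 1L, "}", call. = FALSE)
  }
  invisible(counts)
}

#' Per-class IoU vector
#'
#' @param counts a [confusion_counts()] object.
#' @return numeric vector of per-class IoU; `NA` for classes absent from
#'   both rasters (zero union).
#' @export
class_iou <- function(counts) {
  check_counts(counts)
  union <- counts$tp + counts$fp + counts$fn
  ifelse(union > 0L, counts$tp / union, NA_real_)
}

#' Mean Intersection over Union
#'
#' Mean of per-class IoU over classes with nonzero union; classes absent
#' from both prediction and ground truth are excluded (their IoU is 0/0).
#'
#' @param counts a [confusion_counts()] object.
#' @return a scalar in `[0, 1]`.
#' @export
miou <- function(counts) {
  iou <- class_iou(counts)
  if (all(is.na(iou)))
    stop("no class has nonzero union; mIoU undefined", call. = FALSE)
  mean(iou, na.rm = TRUE)
}

#' Dice coefficient of one class
#' @param counts a [confusion_counts()] object.
#' @param class_index 0-based class index.
#' @return a scalar in `[0, 1]`.
#' @export
dice <- function(counts, class_index) {
  check_counts(counts, class_index)
  i <- class_index + 1L
  denom <- 2 * counts$tp[i] + counts$fp[i] + counts$fn[i]
  if (denom == 0L)
    stop("class ", class_index, " absent from both rasters; Dice undefined",
         call. = FALSE)
  2 * counts$tp[i] / denom
}

#' Jaccard index of one class
#' @inheritParams dice
#' @return a scalar in `[0, 1]`.
#' @export
jaccard <- function(counts, class_index) {
  check_counts(counts, class_index)
  i <- class_index + 1L
  denom <- counts$tp[i] + counts$fp[i] + counts$fn[i]
  if (denom == 0L)
    stop("class ", class_index,
         " absent from both rasters; Jaccard undefined", call. = FALSE)
  counts$tp[i] / denom
}

#' Extract the surface of a binary mask
#'
#' A foreground element is a surface element iff it has a face-adjacent
#' background neighbor (4-connectivity in 2D, 6-connectivity in 3D) or lies
#' on the raster border.
#'
#' @param mask logical or 0/1 matrix (2D) or 3D array.
#' @param spacing physical spacing per axis (recycled; default 1).
#' @return a `surface_set`: integer coordinate matrix (one row per surface
#'   element, columns = axes, 1-based grid indices) with a `spacing`
#'   attribute. Empty foreground yields a 0-row set.
#' @export
extract_surface <- function(mask, spacing = 1) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("`mask` must be a 2D matrix or 3D array", call. = FALSE)
  fg <- array(as.logical(mask), dim = d)
  spacing <- rep_len(as.numeric(spacing), length(d))
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (!any(fg)) {
    coords <- matrix(integer(0), 0, length(d))
  } else {
    # a pixel is interior iff all face neighbors are foreground; borders are
    # surface by convention (treated as adjacent to outside background)
    interior <- fg
    for (ax in seq_along(d)) {
      shift_lo <- shift_along(fg, ax, 1L)   # neighbor at index - 1
      shift_hi <- shift_along(fg, ax, -1L)  # neighbor at index + 1
      interior <- interior & shift_lo & shift_hi
    }
    coords <- which(fg & !interior, arr.ind = TRUE)
    coords <- matrix(as.integer(coords), nrow = nrow(coords))
  }
  structure(coords, spacing = spacing, class = c("surface_set", "matrix"))
}

# Shift a logical array by `by` along axis `ax`, padding with FALSE
# (outside the raster counts as background).
shift_along <- function(x, ax, by) {
  d <- dim(x)
  out <- array(FALSE, dim = d)
  n <- d[ax]
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  if (by == 1L) {        # out[i] = x[i - 1]
    dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1L)
  } else {               # out[i] = x[i + 1]
    dst[[ax]] <- 1:(n - 1L); src[[ax]] <- 2:n
  }
  if (n > 1L)
    out <- do.call(`[<-`, c(list(out), dst,
                            list(value = do.call(`[`, c(list(x), src)))))
  out
}

check_surfaces <- function(A, B) {
  if (!inherits(A, "surface_set") || !inherits(B, "surface_set"))
    stop("arguments must be surface_set objects", call. = FALSE)
  if (nrow(A) == 0L)
    stop("first surface set is empty (no foreground)", call. = FALSE)
  if (nrow(B) == 0L)
    stop("second surface set is empty (no foreground)", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("surface sets have different dimensionality", call. = FALSE)
}

# For each element of A, its Euclidean distance (with spacing applied) to
# the nearest element of B. Chunked full distance computation.
directed_nearest <- function(A, B) {
  sp <- attr(A, "spacing")
  Am <- sweep(unclass(A), 2, sp, `*`)
  Bm <- sweep(unclass(B), 2, attr(B, "spacing"), `*`)
  nb <- nrow(Bm)
  b2 <- rowSums(Bm^2)
  chunk <- max(1L, floor(2e6 / nb))
  out <- numeric(nrow(Am))
  for (start in seq(1L, nrow(Am), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(Am))
    Ai <- Am[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), b2, `+`) - 2 * Ai %*% t(Bm)
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Surface-distance metrics
#'
#' `asd` is the sum of both directed nearest-neighbor distance totals
#' divided by the total number of surface elements; `hd` the larger of the
#' two directed maxima; `hd95` by default the larger of the two directed
#' 95th percentiles (linear interpolation between order statistics), or the
#' 95th percentile of the pooled directed distances if
#' `convention = "pooled"`. All are symmetric in their arguments and
#' satisfy `asd <= hd` and `hd95 <= hd`.
#'
#' @param A,B nonempty `surface_set`s from [extract_surface()].
#' @return a nonnegative scalar in physical units.
#' @export
asd <- function(A, B) {
  check_surfaces(A, B)
  dab <- directed_nearest(A, B)
  dba <- directed_nearest(B, A)
  (sum(dab) + sum(dba)) / (nrow(A) + nrow(B))
}

#' @rdname asd
#' @export
hd <- function(A, B) {
  check_surfaces(A, B)
  max(directed_nearest(A, B), directed_nearest(B, A))
}

#' @rdname asd
#' @param convention `"directed"` (default): max of the two directed 95th
#'   percentiles; `"pooled"`: 95th percentile of all directed distances
#'   pooled together.
#' @export
hd95 <- function(A, B, convention = c("directed", "pooled")) {
  convention <- match.arg(convention)
  check_surfaces(A, B)
  dab <- directed_nearest(A, B)
  dba <- directed_nearest(B, A)
  if (convention == "directed") {
    max(stats::quantile(dab, 0.95, names = FALSE, type = 7),
        stats::quantile(dba, 0.95, names = FALSE, type = 7))
  } else {
    stats::quantile(c(dab, dba), 0.95, names = FALSE, type = 7)
  }
}

#' Full metrics report for a prediction / ground-truth pair
#'
#' @param pred,gt label rasters with classes in `{0..num_classes-1}`.
#' @param num_classes K.
#' @param metrics subset of `c("miou", "dice", "jaccard", "asd", "hd",
#'   "hd95")`.
#' @param spacing physical spacing per axis for surface metrics.
#' @return a `metrics_report` list: `per_class` data frame, aggregate
#'   values, the spacing used, and the classes excluded (absent from both
#'   rasters). Surface metrics of a class empty on either side are `NA`.
#' @export
metrics_report <- function(pred, gt, num_classes,
                           metrics = c("miou", "dice", "jaccard"),
                           spacing = 1) {
  allowed <- c("miou", "dice", "jaccard", "asd", "hd", "hd95")
  metrics <- match.arg(metrics, allowed, several.ok = TRUE)
  counts <- confusion_counts(pred, gt, num_classes)
  K <- counts$num_classes
  union <- counts$tp + counts$fp + counts$fn
  excluded <- which(union == 0L) - 1L
  per_class <- data.frame(class = 0:(K - 1L), iou = class_iou(counts))
  need_surface <- any(metrics %in% c("asd", "hd", "hd95"))
  if ("dice" %in% metrics)
    per_class$dice <- ifelse(union > 0L,
                             2 * counts$tp / (2 * counts$tp + counts$fp +
                                                counts$fn),
                             NA_real_)
  if ("jaccard" %in% metrics)
    per_class$jaccard <- ifelse(union > 0L, counts$tp / union, NA_real_)
  if (need_surface) {
    sa <- sh <- s95 <- rep(NA_real_, K)
    for (i in seq_len(K)) {
      cls <- i - 1L
      Sg <- extract_surface(array(gt == cls, dim = dim_or_len(gt)), spacing)
      Sp <- extract_surface(array(pred == cls, dim = dim_or_len(pred)),
                            spacing)
      if (nrow(Sg) > 0L && nrow(Sp) > 0L) {
        if ("asd" %in% metrics) sa[i] <- asd(Sg, Sp)
        if ("hd" %in% metrics) sh[i] <- hd(Sg, Sp)
        if ("hd95" %in% metrics) s95[i] <- hd95(Sg, Sp)
      }
    }
    if ("asd" %in% metrics) per_class$asd <- sa
    if ("hd" %in% metrics) per_class$hd <- sh
    if ("hd95" %in% metrics) per_class$hd95 <- s95
  }
  agg <- list()
  if ("miou" %in% metrics) agg$miou <- miou(counts)
  for (m in intersect(c("dice", "jaccard", "asd", "hd", "hd95"),
                      metrics))
    agg[[m]] <- mean(per_class[[m]], na.rm = TRUE)
  structure(list(per_class = per_class, aggregate = agg,
                 spacing = rep_len(as.numeric(spacing),
                                   length(dim_or_len(gt))),
                 excluded_classes = excluded),
            class = "metrics_report")
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Aggregate metrics over a set of prediction / ground-truth mask pairs
#'
#' Overlap metrics (mIoU, Dice, Jaccard) are computed from the confusion
#' counts pooled over all pairs; surface metrics are computed per pair and
#' class, then averaged over the pairs in which the class has foreground
#' on both sides.
#'
#' @param pred_list,gt_list lists of congruent label rasters.
#' @inheritParams metrics_report
#' @return a `metrics_report`.
#' @export
eval_mask_pairs <- function(pred_list, gt_list, num_classes,
                            metrics = c("miou", "dice", "jaccard"),
                            spacing = 1) {
  stopifnot(length(pred_list) == length(gt_list), length(gt_list) >= 1L)
  allowed <- c("miou", "dice", "jaccard", "asd", "hd", "hd95")
  metrics <- match.arg(metrics, allowed, several.ok = TRUE)
  overlap <- intersect(metrics, c("miou", "dice", "jaccard"))
  surface <- intersect(metrics, c("asd", "hd", "hd95"))
  report <- metrics_report(unlist(lapply(pred_list, as.integer)),
                           unlist(lapply(gt_list, as.integer)),
                           num_classes,
                           metrics = if (length(overlap)) overlap
                                     else "miou")
  if (!length(overlap)) {
    report$aggregate$miou <- NULL
    report$per_class$iou <- NULL
  }
  if (length(surface)) {
    K <- as.integer(num_classes)
    acc <- matrix(NA_real_, K, length(surface),
                  dimnames = list(NULL, surface))
    tally <- matrix(0L, K, length(surface), dimnames = list(NULL, surface))
    sums <- matrix(0, K, length(surface), dimnames = list(NULL, surface))
    for (j in seq_along(gt_list)) {
      for (i in seq_len(K)) {
        cls <- i - 1L
        Sg <- extract_surface(gt_list[[j]] == cls, spacing)
        Sp <- extract_surface(pred_list[[j]] == cls, spacing)
        if (nrow(Sg) == 0L || nrow(Sp) == 0L) next
        for (m in surface) {
          val <- switch(m, asd = asd(Sg, Sp), hd = hd(Sg, Sp),
                        hd95 = hd95(Sg, Sp))
          sums[i, m] <- sums[i, m] + val
          tally[i, m] <- tally[i, m] + 1L
        }
      }
    }
    for (m in surface) {
      per <- ifelse(tally[, m] > 0L, sums[, m] / tally[, m], NA_real_)
      report$per_class[[m]] <- per
      report$aggregate[[m]] <- mean(per, na.rm = TRUE)
    }
  }
  report$spacing <- rep_len(as.numeric(spacing), 2L)
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (m in names(x$aggregate))
    cat(sprintf("  %-8s %.4f\n", m, x$aggregate[[m]]))
  if (length(x$excluded_classes))
    cat("  excluded classes:", paste(x$excluded_classes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  doc <- list(aggregate = report$aggregate,
              per_class = report$per_class,
              spacing = report$spacing,
              excluded_classes = I(report$excluded_classes))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
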