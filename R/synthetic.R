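#' Synthetic imbalanced segmentation tasks
#'
#' The generator draws 2D grayscale images in which class 0 is background
#' and classes `1..K-1` are geometric shapes whose expected areas decay
#' geometrically with ratio `r` (`0 < r < 1`), painted in increasing class
#' order so later (smaller, rarer) classes overwrite earlier ones. Each
#' class has an intensity signature: pixel intensity = class mean +
#' zero-mean Gaussian noise. This emulates the two difficulties the
#' training method targets — strong class imbalance, and labeled/unlabeled
#' statistics that differ because the labeled subset is small — without
#' requiring any external dataset. Area sampling is stochastic, so minority
#' classes can be absent from individual images, which exercises the
#' absent-class branch of the unlabeled distribution update.
#'
#' @name synthetic-data
NULL

#' Specification of a synthetic dataset
#'
#' @param num_classes K >= 2 (background plus K-1 shape classes).
#' @param image_size `c(H, W)` raster size.
#' @param num_images number of training images.
#' @param num_test number of held-out test images.
#' @param labeled_fraction fraction of training images that keep their
#'   masks, in `(0, 1]`; the count is `max(1, floor(fraction * n))`.
#' @param imbalance_ratio expected area of class `k+1` relative to class
#'   `k`, in `(0, 1)`.
#' @param base_area_fraction expected area of class 1 as a fraction of the
#'   image.
#' @param intensity_means per-class mean intensities in `[0, 1]`; default
#'   evenly spaced from 0.2 to 0.9.
#' @param noise_sigma standard deviation of the additive per-pixel Gaussian
#'   intensity noise.
#' @param image_offset_sd standard deviation of a per-image global
#'   intensity offset, emulating acquisition-level appearance variation
#'   (scanner gain, illumination). This is what makes a small labeled
#'   subset statistically unrepresentative of the unlabeled pool: with few
#'   labeled images only a few offsets are observed with labels, so the
#'   labeled and unlabeled marginal statistics genuinely differ.
#' @param shape_family `"ellipse"`, `"rectangle"` or `"blob"`.
#' @param seed RNG seed; the bundle is a pure function of the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(num_classes = 4, image_size = c(32, 32),
                           num_images = 64, num_test = 16,
                           labeled_fraction = 0.12,
                           imbalance_ratio = 0.4,
                           base_area_fraction = 0.25,
                           intensity_means = NULL,
                           noise_sigma = 0.1,
                           image_offset_sd = 0.15,
                           shape_family = c("ellipse", "rectangle", "blob"),
                           seed = 1L) {
  shape_family <- match.arg(shape_family)
  K <- as.integer(num_classes)
  stopifnot(K >= 2L, length(image_size) == 2L, all(image_size >= 8),
            num_images >= 1, num_test >= 1,
            labeled_fraction > 0, labeled_fraction <= 1,
            imbalance_ratio > 0, imbalance_ratio < 1,
            base_area_fraction > 0, base_area_fraction < 1,
            noise_sigma >= 0, image_offset_sd >= 0)
  if (floor(labeled_fraction * num_images) < 1 && labeled_fraction < 1)
    stopifnot(labeled_fraction * num_images >= 0) # count floor-with-min-1
  if (is.null(intensity_means))
    intensity_means <- seq(0.2, 0.9, length.out = K)
  stopifnot(length(intensity_means) == K)
  if (base_area_fraction * imbalance_ratio * prod(image_size) < 4)
    stop("spec infeasible: class-1 shapes would not fit the raster",
         call. = FALSE)
  structure(list(num_classes = K,
                 image_size = as.integer(image_size),
                 num_images = as.integer(num_images),
                 num_test = as.integer(num_test),
                 labeled_fraction = labeled_fraction,
                 imbalance_ratio = imbalance_ratio,
                 base_area_fraction = base_area_fraction,
                 intensity_means = intensity_means,
                 noise_sigma = noise_sigma,
                 image_offset_sd = image_offset_sd,
                 shape_family = shape_family,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Paint one shape of the given class into the mask; area is the target
# pixel area (before overwriting by later classes).
paint_shape <- function(mask, cls, area, family) {
  H <- nrow(mask); W <- ncol(mask)
  cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
  if (family == "rectangle") {
    aspect <- exp(stats::runif(1, -0.7, 0.7))
    h <- sqrt(area * aspect); w <- area / h
    rows <- pmax(1, round(cy - h / 2)):pmin(H, round(cy + h / 2))
    cols <- pmax(1, round(cx - w / 2)):pmin(W, round(cx + w / 2))
    mask[rows, cols] <- cls
    return(mask)
  }
  # ellipse / blob: implicit quadratic form over the grid
  aspect <- exp(stats::runif(1, -0.5, 0.5))
  theta <- stats::runif(1, 0, pi)
  a <- sqrt(area / pi * aspect); b <- area / pi / a
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (family == "blob") {
    # union of the ellipse with two half-size satellite lobes
    for (k in 1:2) {
      dy <- stats::rnorm(1, 0, a / 2); dx <- stats::rnorm(1, 0, a / 2)
      inside <- inside |
        (((u - dx) / (a / 2))^2 + ((v - dy) / (b / 2))^2 <= 1)
    }
  }
  mask[inside] <- cls
  mask
}

generate_one <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  K <- spec$num_classes
  mask <- matrix(0L, H, W)
  base <- spec$base_area_fraction * H * W
  for (cls in seq_len(K - 1L)) {
    # lognormal area jitter; tiny draws can vanish, leaving the class absent
    area <- base * spec$imbalance_ratio^(cls - 1L) *
      exp(stats::rnorm(1, 0, 0.4))
    if (area >= 1)
      mask <- paint_shape(mask, cls, area, spec$shape_family)
  }
  offset <- stats::rnorm(1, 0, spec$image_offset_sd)
  img <- matrix(spec$intensity_means[mask + 1L], H, W) + offset +
    matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  list(image = img, mask = mask)
}

#' Generate a synthetic dataset bundle
#'
#' Deterministic given the spec (including its seed). Training images are
#' split into a labeled and an unlabeled part by [split_labeled()];
#' unlabeled and test masks are kept for evaluation only.
#'
#' @param spec a [synthetic_spec()].
#' @return a `dataset_bundle`: lists `labeled`, `unlabeled`, `test`, each
#'   with `images` and `masks` (matrices), plus a `manifest` data frame
#'   (`id`, `split`) and the `spec`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed <- function(code) { # local RNG, leaves the global stream alone
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(spec$seed)
    code
  }
  withr_seed({
    train <- lapply(seq_len(spec$num_images), function(i) generate_one(spec))
    test <- lapply(seq_len(spec$num_test), function(i) generate_one(spec))
  })
  bundle <- structure(
    list(labeled = list(images = lapply(train, `[[`, "image"),
                        masks = lapply(train, `[[`, "mask")),
         unlabeled = list(images = list(), masks = list()),
         test = list(images = lapply(test, `[[`, "image"),
                     masks = lapply(test, `[[`, "mask")),
         spec = spec),
    class = "dataset_bundle")
  split_labeled(bundle, spec$labeled_fraction, seed = spec$seed + 1L)
}

#' Split training images into labeled and unlabeled parts
#'
#' Draws a uniformly random labeled subset of size
#' `max(1, floor(fraction * n))` from all training images (labeled and
#' unlabeled pooled); the rest become unlabeled. Deterministic given the
#' seed.
#'
#' @param bundle a `dataset_bundle`.
#' @param labeled_fraction fraction in `(0, 1]`.
#' @param seed RNG seed for the subset draw.
#' @return the re-split `dataset_bundle`.
#' @export
split_labeled <- function(bundle, labeled_fraction, seed = 1L) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (!is.numeric(labeled_fraction) || labeled_fraction <= 0 ||
      labeled_fraction > 1)
    stop("`labeled_fraction` must lie in (0, 1]", call. = FALSE)
  images <- c(bundle$labeled$images, bundle$unlabeled$images)
  masks <- c(bundle$labeled$masks, bundle$unlabeled$masks)
  n <- length(images)
  n_lab <- max(1L, floor(labeled_fraction * n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  lab_idx <- sort(sample.int(n, n_lab))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  unl_idx <- setdiff(seq_len(n), lab_idx)
  bundle$labeled <- list(images = images[lab_idx], masks = masks[lab_idx])
  bundle$unlabeled <- list(images = images[unl_idx], masks = masks[unl_idx])
  bundle$manifest <- data.frame(
    id = c(lab_idx, unl_idx, n + seq_along(bundle$test$images)),
    split = c(rep("labeled", length(lab_idx)),
              rep("unlabeled", length(unl_idx)),
              rep("test", length(bundle$test$images))),
    stringsAsFactors = FALSE)
  bundle
}

#' Empirical per-class pixel frequencies of a bundle
#'
#' @param bundle a `dataset_bundle`.
#' @param splits which splits to pool.
#' @return numeric vector of length K summing to 1.
#' @export
class_frequencies <- function(bundle,
                              splits = c("labeled", "unlabeled", "test")) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  K <- bundle$spec$num_classes
  counts <- numeric(K)
  for (s in splits)
    for (m in bundle[[s]]$masks)
      counts <- counts + tabulate(as.integer(m) + 1L, nbins = K)
  counts / sum(counts)
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(
    "<dataset_bundle: K = %d, %d labeled + %d unlabeled train, %d test>\n",
    x$spec$num_classes, length(x$labeled$images),
    length(x$unlabeled$images), length(x$test$images)))
  invisible(x)
}
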