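#' Lightweight per-pixel segmentation backbone
#'
#' The bundled reference backbone treats segmentation as per-pixel
#' classification: a fixed multi-scale convolutional stem (raw intensity,
#' box means at two window sizes, a local standard deviation) feeds a
#' trainable one-hidden-layer perceptron with a K-way softmax head, applied
#' independently at every pixel. It is deliberately small — reproducible,
#' CPU-friendly, and with closed-form gradients — while exposing exactly
#' the contract the co-training engine needs: a parameterized, seedable
#' function from an image batch to a probability map. Heavier
#' encoder-decoder architectures can be plugged in by implementing the same
#' interface.
#'
#' @name segmentation-model
NULL

# Box mean of a 2D image with window half-width hw (window (2hw+1)^2),
# replicate padding at the borders, via integral image.
box_mean <- function(img, hw) {
  H <- nrow(img); W <- ncol(img)
  pad <- img[c(rep(1, hw), 1:H, rep(H, hw)),
             c(rep(1, hw), 1:W, rep(W, hw)), drop = FALSE]
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum) # t(integral image)
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  k <- 2 * hw + 1
  r1 <- 1:H; c1 <- 1:W
  (cs[r1 + k, c1 + k, drop = FALSE] - cs[r1 + k, c1, drop = FALSE] -
      cs[r1, c1 + k, drop = FALSE] + cs[r1, c1, drop = FALSE]) / k^2
}

#' Fixed convolutional pixel features of an image
#'
#' Seven channels per pixel: raw intensity, box means over 3x3 and 7x7
#' windows, the 3x3 local standard deviation, two center-surround
#' contrasts (intensity minus each box mean) and the deviation from the
#' whole-image mean. The contrast and image-relative channels are
#' invariant to a global intensity offset of the image, which lets the
#' head trade off absolute and relative appearance cues.
#'
#' @param image numeric H x W matrix of intensities.
#' @return numeric matrix `(H*W) x 7`; rows follow R's column-major raster
#'   order.
#' @export
pixel_features <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  x <- as.numeric(image)
  m3 <- as.numeric(box_mean(image, 1L))
  m7 <- as.numeric(box_mean(image, 3L))
  v3 <- pmax(as.numeric(box_mean(image^2, 1L)) - m3^2, 0)
  structure(cbind(x, m3, m7, sqrt(v3), x - m3, x - m7, x - mean(x)),
            pixel_features = TRUE)
}

N_FEATURES <- 7L

#' Create a per-pixel segmentation model
#'
#' Parameters are drawn `N(0, 0.1)` from the model's own seed, so two
#' models with different seeds verifiably differ while any seed reproduces
#' the same initialization.
#'
#' @param num_classes K >= 2.
#' @param seed parameter-initialization seed.
#' @param hidden_units hidden-layer width (default 12); 0 gives a purely
#'   linear softmax head.
#' @return a `seg_model` object.
#' @export
make_model <- function(num_classes, seed, hidden_units = 12L) {
  K <- as.integer(num_classes)
  stopifnot(K >= 2L, hidden_units >= 0L)
  h <- as.integer(hidden_units)
  d <- N_FEATURES
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  params <- if (h > 0L) {
    list(W1 = matrix(stats::rnorm(d * h, 0, 0.1), d, h),
         b1 = numeric(h),
         W2 = matrix(stats::rnorm(h * K, 0, 0.1), h, K),
         b2 = numeric(K))
  } else {
    list(W2 = matrix(stats::rnorm(d * K, 0, 0.1), d, K),
         b2 = numeric(K))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(params = params,
                 velocity = lapply(params, function(p) p * 0),
                 num_classes = K, seed = as.integer(seed),
                 hidden_units = h,
                 architecture_id = sprintf("pixelmlp-d%d-h%d", d, h)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model %s: K = %d, seed = %d>\n",
              x$architecture_id, x$num_classes, x$seed))
  invisible(x)
}

#' Create the co-training model pair
#'
#' Two models with identical architecture but different initialization
#' seeds; equal seeds are refused because they would defeat co-training
#' diversity.
#'
#' @param config a [train_config()].
#' @return list of two `seg_model`s.
#' @export
make_model_pair <- function(config) {
  stopifnot(inherits(config, "train_config"))
  if (config$seed1 == config$seed2)
    stop("seed1 and seed2 must differ: equal seeds give identical models",
         call. = FALSE)
  list(make_model(config$num_classes, config$seed1, config$hidden_units),
       make_model(config$num_classes, config$seed2, config$hidden_units))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass on a feature matrix; keeps the hidden activations for
# backprop. Returns list(logits, probs, hidden).
model_forward <- function(model, X) {
  p <- model$params
  if (model$hidden_units > 0L) {
    Hd <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
    Z <- sweep(Hd %*% p$W2, 2, p$b2, `+`)
  } else {
    Hd <- X
    Z <- sweep(X %*% p$W2, 2, p$b2, `+`)
  }
  list(logits = Z, probs = softmax_rows(Z), hidden = Hd)
}

#' Predict class probabilities for an image
#'
#' @param model a `seg_model`.
#' @param image numeric H x W matrix (or a precomputed feature matrix from
#'   [pixel_features()]).
#' @return a raw `prob_map` with one row per pixel in column-major order.
#' @export
predict_probs <- function(model, image) {
  stopifnot(inherits(model, "seg_model"))
  X <- if (is.matrix(image) && ncol(image) == N_FEATURES &&
           !is.null(attr(image, "pixel_features"))) image
       else pixel_features(image)
  prob_map(model_forward(model, X)$probs, aligned = FALSE)
}

# Backprop from dLoss/dlogits; returns gradients matching params.
model_backward <- function(model, X, fwd, dZ) {
  p <- model$params
  if (model$hidden_units > 0L) {
    gW2 <- crossprod(fwd$hidden, dZ)
    gb2 <- colSums(dZ)
    dH <- dZ %*% t(p$W2) * (1 - fwd$hidden^2)
    list(W1 = crossprod(X, dH), b1 = colSums(dH), W2 = gW2, b2 = gb2)
  } else {
    list(W2 = crossprod(X, dZ), b2 = colSums(dZ))
  }
}

# SGD with momentum: v <- mu*v - eta*g; theta <- theta + v.
model_step <- function(model, grads, lr, momentum) {
  for (nm in names(model$params)) {
    model$velocity[[nm]] <- momentum * model$velocity[[nm]] -
      lr * grads[[nm]]
    model$params[[nm]] <- model$params[[nm]] + model$velocity[[nm]]
  }
  model
}

# Serialize parameters to plain lists (for JSON checkpoints).
model_to_list <- function(model) {
  list(params = lapply(model$params, function(p)
         if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
         else list(dim = NULL, data = as.numeric(p))),
       velocity = lapply(model$velocity, function(p)
         if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
         else list(dim = NULL, data = as.numeric(p))),
       num_classes = model$num_classes, seed = model$seed,
       hidden_units = model$hidden_units,
       architecture_id = model$architecture_id)
}

model_from_list <- function(x) {
  restore <- function(lst) lapply(lst, function(p) {
    v <- as.numeric(p$data)
    if (!is.null(p$dim) && length(p$dim)) matrix(v, p$dim[[1]], p$dim[[2]])
    else v
  })
  structure(list(params = restore(x$params),
                 velocity = restore(x$velocity),
                 num_classes = as.integer(x$num_classes),
                 seed = as.integer(x$seed),
                 hidden_units = as.integer(x$hidden_units),
                 architecture_id = x$architecture_id),
            class = "seg_model")
}
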