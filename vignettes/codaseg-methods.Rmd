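---
title: "Co-training with class-wise distribution alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-training with class-wise distribution alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codaseg)
```

## The problem

Semantic segmentation of biomedical images rarely comes with abundant
pixel-level annotation: masks are expensive, so most available images are
unlabeled. Semi-supervised segmentation exploits both pools. A further,
compounding difficulty is class imbalance — anatomical or surgical-scene
classes can differ in pixel frequency by orders of magnitude — and the fact
that a small labeled subset is not statistically representative of the
unlabeled pool, so the prediction statistics a network develops on
unlabeled data drift away from those it exhibits where supervision exists.

`codaseg` implements a co-training framework that attacks both problems
jointly: two networks exchange pseudo-labels (cross-pseudo supervision),
the class-wise marginal prediction distributions on unlabeled data are
explicitly aligned to those on labeled data, and a dynamic per-class
confidence filter discards pseudo-labels that fall below the class's own
expected confidence.

## The model

### Cross-pseudo supervision

Two networks $F_1, F_2$ share an architecture but start from different
random initializations. On labeled pixels $(x^l, y^l)$ both are trained
with cross-entropy,

$$
L_s = -\tfrac{1}{m}\sum_i \big[\log F_1(x_i^l)_{y_i^l}
      + \log F_2(x_i^l)_{y_i^l}\big],
$$

and on unlabeled pixels each network is supervised by the other network's
hard pseudo-labels (the argmax of its prediction). Disagreement between the
two differently initialized networks is what lets each correct the other's
mistakes.

### Class-wise marginal distributions

Per network, two $K \times K$ matrices are maintained. Row $i$ of the
labeled matrix $M^l$ is an exponential-moving-average (EMA) estimate of the
network's mean predicted probability vector over labeled pixels whose
ground-truth class is $i$:

$$
M_i^l \leftarrow \alpha\, M_i^l + (1-\alpha)\,
\mathrm{mean}\{F(x^l_p) : y^l_p = i\}.
$$

The unlabeled matrix $M^u$ receives the same update grouped by
pseudo-class. Because each row is a *conditional* mean of probability
vectors, every row stays on the probability simplex regardless of class
frequency — this is what makes the later row-wise ratio well defined, and
it is asserted as an invariant throughout the test suite. When a class has
no pseudo-labeled pixel in a batch (typical for minority classes), its
unlabeled row cannot be estimated from data; it is synthesized by applying
the average labeled-to-unlabeled transformation — the entrywise mean over
all $K$ rows of $M^u / M^l$ — to the class's labeled row, then
renormalizing. Averaging over all $K$ rows (rather than only the rows
present in the batch) keeps the branch deterministic and free of
special cases.

### Alignment with adaptive temperature

For an unlabeled pixel whose most probable class is $i$, the prediction is
rescaled by the row-$i$ ratio of the two distributions, with the labeled
row flattened by a per-class temperature $\tau_i = 1 - M^l_{ii}$:

$$
F'(x^u) = \mathrm{Normalize}\big(F(x^u) \otimes (M_i^l)^{\tau_i}
\oslash M_i^u\big).
$$

A class the network already recognizes well on labeled data has a large
diagonal entry, hence a small $\tau_i$ and a near-flat weight — little
interference. A poorly learned (minority) class keeps $\tau_i \approx 1$
and receives the full corrective ratio. Both matrices start uniform at
$1/K$, which makes the transformation an exact identity at step 0, so
alignment introduces no bias before statistics exist. The aligned output
replaces the raw one when pseudo-labels are generated and scored.

### Over-expectation filtering

The diagonal entry $M^u_{ii}$ is the running expectation of the confidence
the network assigns to pseudo-class $i$. It is used as a dynamic, per-class
threshold: a pseudo-label is kept only when its confidence *strictly*
exceeds the expectation for its class,

$$
L_u = \mathbb{E}\big[\,\mathbb{1}[p^u > t(\hat y^u)]
\,(-\log F'(x^u)_{\hat y^u})\,\big], \qquad t(i) = M^u_{ii}.
$$

The expectation is taken over *all* unlabeled pixels with the indicator
inside — rejected pixels contribute zero but stay in the denominator — so
raising thresholds can only shrink the loss, a property the tests assert.
With all thresholds at zero the loss reduces exactly to plain cross-pseudo
supervision, which is also asserted to $10^{-12}$. A static scalar
threshold mode exists solely for ablation comparisons against the dynamic
rule. Both networks take an SGD step on $L_s + \lambda_u L_u$ per
iteration, with $\lambda_u = 1$ by default so the two terms are simply
summed.

### What carries gradients

The distribution matrices, pseudo-labels, confidences and acceptance masks
are statistics: they are computed from predictions but never receive
gradients. Only each network's own (aligned) prediction is differentiated.
Because the alignment weight vector is constant with respect to the
parameters, the aligned softmax is the raw softmax with logits shifted by
the log-weights, and the gradient of the filtered cross-entropy keeps its
standard closed form. This was verified against central finite differences
during development.

## The reference backbone

The bundled backbone treats segmentation as per-pixel classification: a
fixed multi-scale convolutional stem — raw intensity, box means over
$3\times3$ and $7\times7$ windows, a local standard deviation, two
center-surround contrasts, and the deviation from the image mean — feeds a
one-hidden-layer perceptron (12 hidden units by default, hyperbolic
tangent) with a $K$-way softmax head. The contrast channels are invariant
to a global intensity offset of the image; the absolute channels are not,
and the trade-off between the two cue families is exactly what labeled
scarcity makes hard to learn from a handful of images. The backbone is
deliberately tiny: it trains in seconds on a CPU, its gradients are exact,
and every experiment in the test suite is reproducible bit for bit.
Heavier encoder–decoder networks can be substituted by implementing the
same interface (a seedable, parameterized map from an image to a
probability map).

Optimization is SGD with momentum 0.9 and a constant learning rate of 0.5
by default; an optional polynomial decay is available but off by default,
since scheduling is not part of the method's contribution. Labeled and
unlabeled sub-batches (2 and 4 images by default) are drawn independently
each iteration by uniform sampling without replacement — a stateless rule
that keeps checkpoint resumption bit-compatible through the saved RNG
state alone.

## The synthetic benchmark

The generator draws grayscale images in which background (class 0) is
overlaid by $K-1$ shape classes whose expected areas decay geometrically
with ratio $r$; later, rarer classes overwrite earlier ones. Each class
has a mean intensity (evenly spaced in $[0.2, 0.9]$ by default) plus
per-pixel Gaussian noise ($\sigma = 0.1$). Two features matter:

* **Imbalance.** With the default $r = 0.4$ and $K = 4$, the rarest class
  occupies a few percent of the pixels, and stochastic area sampling means
  minority classes are absent from many individual images — which
  exercises the absent-class branch of the unlabeled update in earnest.
* **Acquisition-level appearance shift.** Every image receives a global
  intensity offset drawn from $N(0, 0.15^2)$ — about two thirds of the
  inter-class intensity gap — emulating per-scan gain and illumination
  variation. This is the mechanism that makes a small labeled subset
  genuinely unrepresentative: seven labeled images cover seven offsets,
  while the unlabeled pool spans the distribution. Without such a shift a
  per-pixel classifier saturates from a handful of labeled images and the
  benchmark probes nothing.

What the generator does **not** emulate: spatially correlated noise,
texture, partial-volume boundaries, multi-scale anatomy, or any
photorealistic structure. Passing the bundled experiments therefore shows
that the training machinery behaves as designed under imbalance and
distribution mismatch — not that any particular clinical performance would
be attained.

The default study conditions are $K = 4$, $r = 0.4$, 64 training images of
$32 \times 32$ pixels at a 12% labeled fraction (7 images), 16 test
images, and 1,000 training iterations — small enough that the full
two-arm, three-seed comparison runs in a couple of minutes on one CPU
core, large enough that the supervised baseline is clearly off its
ceiling.

## Numerical choices

* EMA momentum $\alpha = 0.99$ (averaging roughly the last 100
  iterations); the matrices start uniform.
* Every divisor carries an additive guard $\varepsilon = 10^{-8}$, and
  $0^\tau$ is evaluated as $\varepsilon^\tau$.
* The temperature is clamped to $[0.05, 1]$: $\tau \to 0$ against a zero
  entry in a labeled row is ill-conditioned.
* Probabilities inside logarithms are floored at $10^{-12}$, so losses are
  finite for any input.
* Argmax ties break toward the lowest class index, fixed for bit-stability.
* Thresholds use strict inequality; a confidence exactly at its class
  threshold is rejected.
* The 95th-percentile Hausdorff distance takes the larger of the two
  directed 95th percentiles (linear interpolation between order
  statistics); the pooled-percentile convention is available as an option.
* Surface elements are foreground pixels with a face-adjacent background
  neighbor (4-connectivity in 2D, 6-connectivity in 3D) or on the raster
  border.
* mIoU excludes classes absent from both rasters (0/0 unions).
* A labeled class absent from a batch keeps its previous row; the
  inverse-transformation trick applies to the unlabeled matrix only.

## Design choices that were genuinely open

* **Conditional row semantics.** The labeled update's expectation is read
  as the mean over pixels *of* class $i$, not the unconditional mean
  scaled by class frequency. The conditional reading keeps rows on the
  simplex and makes the uniform-matrix identity exact; the unconditional
  one would couple the alignment ratio to class frequency and break it.
* **The absent-class expectation.** The mean in the inverse transformation
  is taken entrywise over the $K$ rows of the ratio matrix. A scalar mean
  of the single absent row's ratio would renormalize back to the labeled
  row exactly, making the branch a no-op.
* **Confidence source.** Pseudo-label confidences are read from the
  aligned output, which replaces the raw output everywhere downstream of
  alignment; the self-side of the filtered loss is likewise the aligned
  prediction.
* **Per-model state.** Each network owns its own $(M^l, M^u)$ pair and its
  own thresholds; nothing is shared between the two except the exchanged
  pseudo-labels.
* **No warm-up ramp.** $L_u$ enters at full weight from iteration 1; the
  over-expectation filter itself suppresses the (many) low-confidence
  pseudo-labels of early training, which is the role a ramp would play.
* **Update order within an iteration**: labeled matrices first, then
  unlabeled matrices (whose absent-class branch therefore sees the current
  labeled rows), then pseudo-label generation, then the losses.

## A worked micro-example

```{r alignment-example}
cfg <- ema_config()
Ml <- init_distributions(2, "labeled")
Ml$entries <- matrix(c(0.6, 0.4, 0.5, 0.5), 2, byrow = TRUE)
Mu <- init_distributions(2, "unlabeled")
Mu$entries <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, byrow = TRUE)
p <- prob_map(matrix(c(0.7, 0.3), 1))
align_prediction(p, Ml, Mu, cfg)$values
```

The pixel's argmax class is 0, whose temperature is
$1 - 0.6 = 0.4$; the weight vector $(0.6, 0.4)^{0.4} / (0.8, 0.2)$
penalizes class 0 (over-represented on unlabeled data, $0.8 > 0.6$) enough
that the aligned prediction flips toward class 1. This is the intended
behavior: a class the unlabeled statistics over-favor relative to the
labeled ones is down-weighted, and the argmax may legitimately change.

## A small training run

```{r train-example}
bundle <- generate_bundle(synthetic_spec(num_images = 16, num_test = 4,
                                         image_size = c(24, 24),
                                         labeled_fraction = 0.25,
                                         seed = 3))
cfg <- train_config(max_iterations = 300, val_interval = 100)
fit <- train(cfg, bundle$labeled, bundle$unlabeled,
             list(images = bundle$test$images, masks = bundle$test$masks))
fit$log$validation[, c("iteration", "miou")]
```

## Known limitations

* The backbone is per-pixel: it has no learnable spatial context beyond
  its fixed feature windows, so it cannot model shape priors. It exists to
  exercise the training machinery reproducibly, not to compete with
  encoder–decoder networks.
* Distribution statistics are estimated per model from small batches; with
  very small unlabeled batches and many classes, most rows are carried by
  the absent-class branch for long stretches.
* The generator is 2D; volumetric data is supported on the metric side
  (3D surface distances) but not by the trainer.
* Physical spacing is taken as given; no resampling or registration.
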