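# Fixture builders and independent oracles shared across the test files.

# Random probability map: n pixels, K classes, rows on the simplex.
random_prob_map <- function(n, K, aligned = FALSE) {
  V <- matrix(stats::rexp(n * K), n, K)
  prob_map(V / rowSums(V), aligned = aligned)
}

# Random class_dist with simplex rows.
random_class_dist <- function(K, role = "labeled") {
  M <- init_distributions(K, role)
  E <- matrix(stats::rexp(K * K) + 0.05, K, K)
  M$entries <- E / rowSums(E)
  M
}

# Scalar EMA recursion iterated n times: the independent oracle for the
# closed form p + alpha^n (r0 - p).
iterate_ema <- function(r0, p, alpha, n) {
  r <- r0
  for (i in seq_len(n)) r <- alpha * r + (1 - alpha) * p
  r
}

# All-pairs brute-force surface distances between two coordinate matrices
# (rows = points), with per-axis spacing. Returns the directed
# nearest-distance vectors both ways.
brute_force_directed <- function(A, B, spacing = 1) {
  sp <- rep_len(spacing, ncol(A))
  Am <- sweep(A, 2, sp, `*`)
  Bm <- sweep(B, 2, sp, `*`)
  dab <- apply(Am, 1, function(a)
    min(sqrt(colSums((t(Bm) - a)^2))))
  dba <- apply(Bm, 1, function(b)
    min(sqrt(colSums((t(Am) - b)^2))))
  list(ab = dab, ba = dba)
}

as_surface <- function(coords, spacing = 1) {
  structure(matrix(as.integer(coords), nrow = nrow(coords)),
            spacing = rep_len(as.numeric(spacing), ncol(coords)),
            class = c("surface_set", "matrix"))
}

# Tiny deterministic dataset for engine tests.
tiny_bundle <- function(seed = 5, num_images = 10, image_size = c(16, 16),
                        ...) {
  generate_bundle(synthetic_spec(num_images = num_images, num_test = 4,
                                 image_size = image_size,
                                 labeled_fraction = 0.2, seed = seed, ...))
}
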