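# Independent oracles and small fixture builders used across the tests.

# Structure-tensor dominant orientation, degrees in (-90, 90], positive when
# structures descend to the right. Central differences, independent of the
# package's Sobel/histogram estimator.
structure_tensor_orientation <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- (img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]) / 2
  gy <- (img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]) / 2
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  grad_dir <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  ang <- grad_dir + 90  # edge direction is perpendicular to the gradient
  ang <- ((ang + 90) %% 180) - 90
  if (ang == -90) ang <- 90 else ang
}

# Flat horizontal layer pair with a given gap.
flat_layer_set <- function(gap, n = 100, top = 30) {
  a <- layer_curve(seq_len(n), rep(top, n))
  b <- layer_curve(seq_len(n), rep(top + gap, n))
  layer_set(a, a, b, confidence = 1)
}

# 45-degree parallel lines with a vertical offset.
tilted_pair <- function(offset = 20, n = 200) {
  list(inner = layer_curve(seq_len(n), seq_len(n) + 10),
       cornea = layer_curve(seq_len(n), seq_len(n) + 10 + offset))
}

# Smooth random curve pair (lens above cornea) for property checks.
random_curve_pair <- function(n = 120, seed = 1) {
  set.seed(seed)
  x <- seq_len(n)
  base <- 60 + 30 * sin(x / runif(1, 20, 60)) + cumsum(rnorm(n, 0, 0.3))
  gap <- runif(1, 5, 40) + 5 * sin(x / runif(1, 15, 50))
  list(inner = layer_curve(x, base), cornea = layer_curve(x, base + pmax(gap, 1)))
}

# Small, quick phantom used where full size is unnecessary.
small_phantom <- function(scenario = "central", rotation_deg = 0,
                          speckle_sigma = 0, seed = 1, width = 160,
                          height = 140) {
  generate_phantom(phantom_spec(
    width = width, height = height, scenario = scenario, vault = 18,
    rotation_deg = rotation_deg, speckle_sigma = speckle_sigma,
    cornea_apex_row = 75, cornea_curv = 2e-3, seed = seed))
}

# Step-edge image: bright below `edge_row`.
step_image <- function(edge_row = 60, h = 120, w = 150, hi = 200) {
  img <- matrix(0, h, w)
  img[edge_row:h, ] <- hi
  img
}

# Simple bilinear sampler for round-trip comparisons.
bilinear_at <- function(m, r, c) {
  r0 <- pmax(1, pmin(floor(r), nrow(m) - 1)); c0 <- pmax(1, pmin(floor(c), ncol(m) - 1))
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc + m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
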