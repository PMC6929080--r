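#' Snake (active contour) configuration
#'
#' @param alpha Elasticity weight on squared first differences.
#' @param beta Rigidity weight on squared second differences.
#' @param edge_weight Weight of the external (image potential) energy.
#' @param max_iter Iteration cap.
#' @param move_radius Maximum vertical node move per iteration, px.
#' @param conv_tol Convergence: stop when fewer than this fraction of nodes
#'   moved in an iteration.
#' @return A `snake_config` list.
#' @export
snake_config <- function(alpha = 50, beta = 20, edge_weight = 1,
                         max_iter = 400, move_radius = 2, conv_tol = 0.01) {
  if (alpha < 0 || beta < 0 || edge_weight < 0)
    stop("alpha, beta and edge_weight must be >= 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(alpha = alpha, beta = beta, edge_weight = edge_weight,
                 max_iter = max_iter, move_radius = move_radius,
                 conv_tol = conv_tol), class = "snake_config")
}

#' Internal energy of a discrete open contour
#'
#' Discrete form of the elasticity + rigidity functional: the sum of
#' `alpha * |v_{i+1} - v_i|^2` over segments plus
#' `beta * |v_{i-1} - 2 v_i + v_{i+1}|^2` over interior nodes.
#'
#' @param nodes Numeric matrix with columns `(col, row)`, one node per row;
#'   at least 3 nodes.
#' @param alpha,beta Non-negative weights.
#' @return Scalar energy.
#' @export
internal_energy <- function(nodes, alpha, beta) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) < 3) stop("need at least 3 nodes")
  d1 <- diff(nodes)
  d2 <- diff(nodes, differences = 2)
  alpha * sum(d1^2) + beta * sum(d2^2)
}

#' Image potential for the external energy
#'
#' Gradient magnitude of the image, Gaussian-smoothed to widen the capture
#' range, negated and min-max normalized to `[-255, 0]` so that minima lie
#' on edges and the potential is commensurate with 8-bit intensities.
#'
#' @param img Grayscale matrix.
#' @param sigma Gaussian smoothing of the gradient magnitude, px.
#' @return Matrix of potential values in `[-255, 0]`.
#' @export
snake_potential <- function(img, sigma = 2) {
  gr <- sobel_gradients(img)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  mag <- .from_ebimage(EBImage::gblur(EBImage::Image(t(mag) / 255),
                                      sigma = sigma))
  rng <- range(mag)
  if (diff(rng) < 1e-12) return(matrix(0, nrow(img), ncol(img)))
  -255 * (mag - rng[1]) / (rng[2] - rng[1])
}

# Bilinear sample of a field at (row, col) points, clamped to the border.
bilinear_sample <- function(field, row, col) {
  h <- nrow(field); w <- ncol(field)
  r <- pmin(pmax(row, 1), h); c2 <- pmin(pmax(col, 1), w)
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c2), w - 1L)
  fr <- r - r0; fc <- c2 - c0
  i00 <- (c0 - 1) * h + r0
  v00 <- field[i00];       v10 <- field[i00 + 1]
  v01 <- field[i00 + h];   v11 <- field[i00 + h + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' External energy at a point
#'
#' @param point `c(col, row)`.
#' @param potential Field from [snake_potential()].
#' @param weight Non-negative weight.
#' @return Scalar: `weight` times the bilinear potential sample. Points
#'   outside the field are clamped and flagged with attribute `clamped`.
#' @export
external_energy <- function(point, potential, weight) {
  col <- point[1]; row <- point[2]
  clamped <- row < 1 || row > nrow(potential) ||
    col < 1 || col > ncol(potential)
  structure(weight * bilinear_sample(potential, row, col), clamped = clamped)
}

# Local energy contribution of node i at candidate rows y (vectorized over
# nodes): all alpha/beta terms that involve y_i, plus the external term.
.local_energy <- function(y, idx, rows, xs, pot_cols, cfg) {
  n <- length(rows)
  at <- function(j) ifelse(j >= 1 & j <= n, rows[pmin(pmax(j, 1), n)], NA)
  ym1 <- at(idx - 1); yp1 <- at(idx + 1)
  ym2 <- at(idx - 2); yp2 <- at(idx + 2)
  e <- cfg$edge_weight * bilinear_sample(pot_cols$field, y, xs[idx])
  a <- cfg$alpha
  e <- e + ifelse(is.na(ym1), 0, a * (1 + (y - ym1)^2))
  e <- e + ifelse(is.na(yp1), 0, a * (1 + (yp1 - y)^2))
  b <- cfg$beta
  e <- e + ifelse(is.na(ym1) | is.na(yp1), 0, b * (ym1 - 2 * y + yp1)^2)
  e <- e + ifelse(is.na(ym2) | is.na(ym1), 0, b * (ym2 - 2 * ym1 + y)^2)
  e <- e + ifelse(is.na(yp1) | is.na(yp2), 0, b * (y - 2 * yp1 + yp2)^2)
  e
}

# Total snake energy (internal on (col,row) nodes + external), for the trace.
.total_energy <- function(rows, xs, potential, cfg) {
  nodes <- cbind(xs, rows)
  internal_energy(nodes, cfg$alpha, cfg$beta) +
    cfg$edge_weight * sum(bilinear_sample(potential, rows, xs))
}

#' Refine a curve with a greedy open snake
#'
#' One node per image column; nodes (including the free end nodes) move
#' vertically within `move_radius` of their current position to the lowest
#' local-energy position. Updates proceed in three interleaved sweeps
#' (nodes `i`, `i+3`, ... share no energy term), so each sweep is exact
#' coordinate descent and the total energy never increases. Stops when fewer
#' than `conv_tol` of the nodes moved or after `max_iter` iterations.
#'
#' @param initial A [layer_curve()] with at least 5 points.
#' @param img Grayscale matrix (the potential is derived from it), or a
#'   precomputed potential passed via `potential`.
#' @param cfg A [snake_config()].
#' @param potential Optional precomputed [snake_potential()] field.
#' @return The refined [layer_curve()], with attribute `energy_trace`
#'   (total energy per iteration, non-increasing).
#' @export
evolve <- function(initial, img, cfg = snake_config(), potential = NULL) {
  if (length(initial$cols) < 5) stop("degenerate initial curve (<5 points)")
  if (is.null(potential)) potential <- snake_potential(img)
  xs <- as.numeric(initial$cols)
  rows <- initial$rows
  n <- length(rows)
  offs <- seq(-cfg$move_radius, cfg$move_radius)
  pot <- list(field = potential)
  trace <- .total_energy(rows, xs, potential, cfg)
  for (it in seq_len(cfg$max_iter)) {
    moved <- 0L
    for (phase in 0:2) {
      idx <- which(seq_len(n) %% 3L == phase)
      if (length(idx) == 0L) next
      cur <- .local_energy(rows[idx], idx, rows, xs, pot, cfg)
      best <- cur; besty <- rows[idx]
      for (o in offs) {
        if (o == 0) next
        y <- rows[idx] + o
        e <- .local_energy(y, idx, rows, xs, pot, cfg)
        upd <- e < best - 1e-12
        besty[upd] <- y[upd]; best[upd] <- e[upd]
      }
      ch <- besty != rows[idx]
      moved <- moved + sum(ch)
      rows[idx] <- besty
    }
    trace <- c(trace, .total_energy(rows, xs, potential, cfg))
    if (moved < cfg$conv_tol * n) break
  }
  out <- layer_curve(initial$cols, rows, initial$provenance)
  attr(out, "energy_trace") <- trace
  out
}
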