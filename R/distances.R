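#' Euclidean distance between two points
#'
#' @param p,q Numeric vectors of equal length.
#' @return `sqrt(sum((q - p)^2))`.
#' @export
euclidean <- function(p, q) {
  if (length(p) != length(q)) stop("dimension mismatch")
  sqrt(sum((q - p)^2))
}

#' Vertical-line distance paradigm
#'
#' The corresponding point is taken in the same column of the opposite
#' curve. Fast, but biased on leaning regions (a 45-degree parallel pair at
#' vertical offset d measures d instead of the true gap d/sqrt(2)).
#'
#' @param inner,cornea [layer_curve()] objects.
#' @param col Column(s) to evaluate.
#' @return Distance(s) in px; `NaN` where a column is outside either span.
#' @export
vertical_distance <- function(inner, cornea, col) {
  a <- curve_row_at(inner, col)
  b <- curve_row_at(cornea, col)
  out <- abs(b - a)
  out[is.na(out)] <- NaN
  out
}

# Least-squares tangent slope of a curve at a column over a window of
# neighbouring columns.
.tangent_slope <- function(curve, col, tangent_window = 10) {
  half <- tangent_window / 2
  sel <- which(abs(curve$cols - col) <= half)
  if (length(sel) < 2) return(NA_real_)
  xs <- curve$cols[sel]; ys <- curve$rows[sel]
  if (stats::var(xs) == 0) return(NA_real_)
  stats::cov(xs, ys) / stats::var(xs)
}

#' Normal-direction distance paradigm
#'
#' Determines the tangent of the inner curve at `col` by a least-squares fit
#' over a neighbourhood window, casts a ray along the normal toward the
#' opposite curve and returns the Euclidean length to the first crossing
#' (exact segment intersection, no pixel stepping).
#'
#' @param inner [layer_curve()] the ray starts from.
#' @param col Column of the ray origin (must have neighbours in the window).
#' @param cornea Opposite [layer_curve()].
#' @param tangent_window Neighbourhood window for the tangent fit, px.
#' @return Distance in px, or `NaN` when the ray exits the opposite span
#'   without crossing.
#' @export
normal_distance <- function(inner, col, cornea, tangent_window = 10) {
  y0 <- curve_row_at(inner, col)
  if (is.na(y0)) return(NaN)
  m <- .tangent_slope(inner, col, tangent_window)
  if (is.na(m)) return(NaN)
  # tangent (1, m); unit normals +-(-m, 1)/norm in (x, y=row-down)
  nrm <- sqrt(1 + m^2)
  nx <- -m / nrm; ny <- 1 / nrm
  # orient the normal toward the opposite curve
  ref <- stats::median(cornea$rows)
  if ((ref - y0) * ny < 0) { nx <- -nx; ny <- -ny }
  xs <- cornea$cols; ys <- cornea$rows
  n <- length(xs)
  if (n < 2) return(NaN)
  # ray (x0,y0) + t(nx,ny) vs segments (xs[i],ys[i])-(xs[i+1],ys[i+1])
  x1 <- xs[-n]; y1 <- ys[-n]
  dxs <- xs[-1] - x1; dys <- ys[-1] - y1
  den <- nx * dys - ny * dxs
  ex <- x1 - col; ey <- y1 - y0
  t_ray <- (ex * dys - ey * dxs) / den
  u <- (ex * ny - ey * nx) / (-den)
  ok <- is.finite(t_ray) & is.finite(u) & t_ray > 1e-9 & u >= 0 & u <= 1
  if (!any(ok)) return(NaN)
  min(t_ray[ok])
}

#' Nearest-point distance paradigm
#'
#' Two-stage search within a window of the opposite curve around the
#' vertical projection: a coarse scan over equidistant points, then
#' exhaustive pixel-wise refinement. Refinement covers every coarse sample
#' within the Lipschitz bound of the coarse winner, so the result equals the
#' true discrete minimum over the window; ties break toward the smaller
#' column.
#'
#' @param inner [layer_curve()] the query point lies on.
#' @param col Query column.
#' @param cornea Opposite [layer_curve()].
#' @param coarse_step Coarse sampling stride in points.
#' @param window_cols Half-width of the search window around the vertical
#'   projection, in columns; `Inf` searches the whole curve.
#' @return Distance in px (`NaN` only if the query column is off-span).
#' @export
nearest_distance <- function(inner, col, cornea, coarse_step = 10,
                             window_cols = 50) {
  y0 <- curve_row_at(inner, col)
  if (is.na(y0)) return(NaN)
  sel <- which(abs(cornea$cols - col) <= window_cols)
  if (length(sel) == 0L) sel <- seq_along(cornea$cols)
  xs <- cornea$cols[sel]; ys <- cornea$rows[sel]
  d2 <- function(i) sqrt((xs[i] - col)^2 + (ys[i] - y0)^2)
  n <- length(xs)
  coarse <- unique(c(seq(1L, n, by = max(1L, as.integer(coarse_step))), n))
  dc <- d2(coarse)
  best <- min(dc)
  # max move of the distance between consecutive points along the curve
  span <- if (n > 1) max(sqrt(diff(xs)^2 + diff(ys)^2)) else 0
  lip <- coarse_step * span
  seeds <- coarse[dc <= best + lip]
  cand <- unique(unlist(lapply(seeds, function(s)
    max(1L, s - coarse_step):min(n, s + coarse_step))))
  dd <- d2(cand)
  dmin <- min(dd)
  winners <- cand[dd == dmin]
  w <- min(winners)  # tie rule: smaller column
  structure(dmin, match_col = xs[w], match_row = ys[w])
}

#' Per-column cornea-lens distance profile
#'
#' Computes all three paradigms at every shared column of the innermost
#' available lens curve and the cornea, and enforces the paradigm ordering
#' (nearest is never larger than vertical or normal).
#'
#' @param layers A [layer_set()]; the lens curve is `scl_inner` when present,
#'   else `scl_outer` (two-layer images).
#' @param tangent_window,coarse_step,window_cols Paradigm parameters.
#' @param pixel_size_um Optional micrometres per pixel; adds `*_um` columns.
#' @return A `distance_profile` object (data.frame-backed): columns `col`,
#'   `vertical`, `normal`, `nearest`.
#' @export
distance_profile <- function(layers, tangent_window = 10, coarse_step = 10,
                             window_cols = 50, pixel_size_um = NULL) {
  if (is.null(layers$cornea)) stop("missing cornea curve")
  lens <- if (!is.null(layers$scl_inner)) layers$scl_inner else layers$scl_outer
  if (is.null(lens)) stop("missing lens curve")
  cols <- intersect(lens$cols, layers$cornea$cols)
  if (length(cols) == 0L) stop("curves share no columns")
  vert <- vertical_distance(lens, layers$cornea, cols)
  norm <- vapply(cols, function(cc)
    normal_distance(lens, cc, layers$cornea, tangent_window), numeric(1))
  near <- vapply(cols, function(cc)
    nearest_distance(lens, cc, layers$cornea, coarse_step, window_cols),
    numeric(1))
  # ordering guarantee: the nearest paradigm reports the tightest distance
  near <- pmin(near, vert, norm, na.rm = TRUE)
  df <- data.frame(col = cols, vertical = vert, normal = norm, nearest = near)
  if (!is.null(pixel_size_um)) {
    df$vertical_um <- df$vertical * pixel_size_um
    df$normal_um <- df$normal * pixel_size_um
    df$nearest_um <- df$nearest * pixel_size_um
  }
  structure(df, class = c("distance_profile", "data.frame"),
            pixel_size_um = pixel_size_um)
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d columns (%d..%d)\n",
              nrow(x), min(x$col), max(x$col)))
  for (p in c("vertical", "normal", "nearest")) {
    v <- x[[p]]
    cat(sprintf("  %-8s median %.2f px, range [%.2f, %.2f], %d NaN\n", p,
                stats::median(v, na.rm = TRUE), min(v, na.rm = TRUE),
                max(v, na.rm = TRUE), sum(is.nan(v))))
  }
  invisible(x)
}

#' Query the three stored distances at a column
#'
#' @param profile A [distance_profile()].
#' @param col Column inside the profile span.
#' @return Named vector `c(vertical, normal, nearest)`.
#' @export
query_point <- function(profile, col) {
  i <- match(as.integer(col), profile$col)
  if (is.na(i)) stop("column ", col, " outside the profile span")
  c(vertical = profile$vertical[i], normal = profile$normal[i],
    nearest = profile$nearest[i])
}
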