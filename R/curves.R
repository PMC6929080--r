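#' Layer boundary curves
#'
#' A `layer_curve` is an ordered sub-pixel boundary polyline with exactly one
#' row per image column over a contiguous column span. `rows` may be
#' fractional; `provenance` records per column whether the point was traced
#' from image evidence, interpolated across a gap, or extrapolated.
#'
#' @param cols Integer vector of consecutive column indices.
#' @param rows Numeric vector of row positions (same length as `cols`).
#' @param provenance Character vector: `"traced"`, `"interpolated"` or
#'   `"extrapolated"` per column (recycled if length 1).
#' @return An object of class `layer_curve`.
#' @export
layer_curve <- function(cols, rows, provenance = "traced") {
  cols <- as.integer(cols)
  if (length(cols) == 0L) stop("layer_curve needs at least one column")
  if (any(diff(cols) != 1L)) stop("layer_curve column span must be contiguous")
  if (length(rows) != length(cols)) stop("rows and cols lengths differ")
  if (any(!is.finite(rows))) stop("layer_curve rows must be finite")
  provenance <- rep_len(as.character(provenance), length(cols))
  ok <- provenance %in% c("traced", "interpolated", "extrapolated")
  if (!all(ok)) stop("unknown provenance value: ", provenance[!ok][1])
  structure(list(cols = cols, rows = as.numeric(rows), provenance = provenance),
            class = "layer_curve")
}

#' @export
print.layer_curve <- function(x, ...) {
  cat(sprintf("<layer_curve> cols %d..%d (%d points), rows %.1f..%.1f\n",
              min(x$cols), max(x$cols), length(x$cols),
              min(x$rows), max(x$rows)))
  tb <- table(x$provenance)
  cat("  provenance:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.layer_curve <- function(x, ...) {
  data.frame(col = x$cols, row = x$rows, provenance = x$provenance,
             stringsAsFactors = FALSE)
}

#' Row position of a curve at given columns
#'
#' @param curve A [layer_curve()].
#' @param cols Columns to query; `NA` is returned outside the span.
#' @param interpolate Linearly interpolate at fractional columns.
#' @return Numeric vector of rows.
#' @export
curve_row_at <- function(curve, cols, interpolate = FALSE) {
  if (interpolate) {
    out <- stats::approx(curve$cols, curve$rows, xout = cols, rule = 1)$y
    return(out)
  }
  idx <- match(as.integer(round(cols)), curve$cols)
  curve$rows[idx]
}

#' Rigid rotation transform between image frames
#'
#' Describes the resampling geometry used throughout the package: content is
#' rotated clockwise on screen (rows downward) by `angle` degrees about the
#' image centre, on a canvas expanded to contain the whole rotated frame.
#' Continuous coordinates place the centre of pixel `(row, col)` at
#' `(x, y) = (col - 0.5, row - 0.5)`.
#'
#' @param angle Rotation in degrees, `|angle| <= 90`.
#' @param dim_in `c(height, width)` of the source image.
#' @return List with `dim_out`, and `fwd(points)` / `inv(points)` mapping
#'   matrices of `(row, col)` points between the frames.
#' @export
rotation_transform <- function(angle, dim_in) {
  stopifnot(abs(angle) <= 90, length(dim_in) == 2)
  th <- angle * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  h <- dim_in[1]; w <- dim_in[2]
  wo <- ceiling(w * abs(c2) + h * abs(s2))
  ho <- ceiling(w * abs(s2) + h * abs(c2))
  R <- matrix(c(c2, -s2, s2, c2), 2, 2, byrow = TRUE)  # (x, y) col-vectors
  cin <- c(w / 2, h / 2); cout <- c(wo / 2, ho / 2)
  off <- cout - as.vector(R %*% cin)
  to_xy <- function(rc) cbind(rc[, 2] - 0.5, rc[, 1] - 0.5)
  to_rc <- function(xy) cbind(xy[, 2] + 0.5, xy[, 1] + 0.5)
  list(
    angle = angle, dim_in = dim_in, dim_out = c(ho, wo), R = R, off = off,
    fwd = function(points) {
      xy <- to_xy(as.matrix(points))
      to_rc(sweep(xy %*% t(R), 2, off, `+`))
    },
    inv = function(points) {
      xy <- sweep(to_xy(as.matrix(points)), 2, off, `-`)
      to_rc(xy %*% R)  # R^-1 = t(R); xy %*% R == t(t(R) %*% t(xy))
    }
  )
}

# Transform a layer_curve through a rotation_transform (direction: "fwd"/"inv")
# and resample to one row per integer column of the target frame.
transform_curve <- function(curve, tr, direction = c("fwd", "inv")) {
  direction <- match.arg(direction)
  f <- if (direction == "fwd") tr$fwd else tr$inv
  pts <- f(cbind(curve$rows, curve$cols))
  o <- order(pts[, 2])
  xr <- pts[o, 2]; yr <- pts[o, 1]
  dim_t <- if (direction == "fwd") tr$dim_out else tr$dim_in
  lo <- max(1L, ceiling(min(xr))); hi <- min(dim_t[2], floor(max(xr)))
  if (hi < lo) stop("curve maps outside the target frame")
  cols <- lo:hi
  rows <- stats::approx(xr, yr, xout = cols, rule = 1, ties = mean)$y
  keep <- is.finite(rows)
  prov <- stats::approx(xr, as.numeric(factor(curve$provenance[o],
            levels = c("traced", "interpolated", "extrapolated"))),
            xout = cols, method = "constant", rule = 2, ties = "ordered")$y
  layer_curve(cols[keep], rows[keep],
              c("traced", "interpolated", "extrapolated")[round(prov[keep])])
}
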