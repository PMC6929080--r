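#' Render the cornea-lens distance heatmap
#'
#' Draws the lens inner curve over the grayscale image as a 3-px-thick
#' polyline colored by distance: red at the minimum, green at the maximum,
#' linear RGB interpolation in between (a degenerate constant profile is
#' all red). Columns with undefined distance are left uncolored.
#'
#' @param img Grayscale matrix the curves were measured on.
#' @param layers A [layer_set()].
#' @param profile A [distance_profile()].
#' @param paradigm `"vertical"`, `"normal"` or `"nearest"`.
#' @return A `heatmap_render`: `rgb` array (h x w x 3 in `[0,1]`), `range`
#'   of finite distances and the paradigm used.
#' @export
render_heatmap <- function(img, layers, profile,
                           paradigm = c("nearest", "vertical", "normal")) {
  paradigm <- match.arg(paradigm)
  d <- profile[[paradigm]]
  if (all(!is.finite(d))) stop("all distances are undefined for ", paradigm)
  rng <- range(d[is.finite(d)])
  t <- if (diff(rng) < 1e-12) rep(0, length(d)) else (d - rng[1]) / diff(rng)
  base <- clip255(img) / 255
  rgb <- array(rep(base, 3L), dim = c(nrow(img), ncol(img), 3L))
  lens <- if (!is.null(layers$scl_inner)) layers$scl_inner else layers$scl_outer
  rows0 <- curve_row_at(lens, profile$col)
  h <- nrow(img)
  for (i in seq_along(profile$col)) {
    if (!is.finite(d[i]) || !is.finite(rows0[i])) next
    r <- as.integer(round(rows0[i])) + (-1L:1L)  # 3-px-thick stroke
    r <- r[r >= 1L & r <= h]
    cc <- profile$col[i]
    rgb[r, cc, 1] <- 1 - t[i]   # red at min
    rgb[r, cc, 2] <- t[i]       # green at max
    rgb[r, cc, 3] <- 0
  }
  structure(list(rgb = rgb, range = rng, paradigm = paradigm),
            class = "heatmap_render")
}

#' @export
print.heatmap_render <- function(x, ...) {
  cat(sprintf("<heatmap_render> %dx%d, %s paradigm, range [%.2f, %.2f] px\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$paradigm,
              x$range[1], x$range[2]))
  invisible(x)
}

#' Write a heatmap render as PNG
#'
#' @param hm A `heatmap_render`.
#' @param path Output path.
#' @export
write_heatmap <- function(hm, path) {
  png::writePNG(hm$rgb, path)
  invisible(path)
}

#' @export
plot.heatmap_render <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 2, 0)); on.exit(graphics::par(op))
  graphics::plot(c(0, dim(x$rgb)[2]), c(0, dim(x$rgb)[1]), type = "n",
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = paste("cornea-lens distance,", x$paradigm))
  graphics::rasterImage(x$rgb, 0, 0, dim(x$rgb)[2], dim(x$rgb)[1])
  invisible(x)
}
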