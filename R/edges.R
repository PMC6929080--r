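#' Canny edge detection
#'
#' Standard Canny chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and two-threshold
#' hysteresis (weak edge pixels are kept only when 8-connected to a strong
#' one). Thresholds apply to the raw Sobel L2 magnitude on the 0-255
#' intensity scale.
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param low,high Hysteresis thresholds, `0 <= low <= high`.
#' @param kernel Odd Sobel aperture; apertures above 3 are emulated by extra
#'   Gaussian pre-smoothing.
#' @return An `edge_map` object: logical matrix `edges` plus a `params_echo`.
#' @export
detect_edges <- function(img, low = 90, high = 120, kernel = 3) {
  validate_gray_image(img)
  if (low < 0 || low > high) stop("need 0 <= low <= high")
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  sm <- .from_ebimage(EBImage::gblur(.as_ebimage(clip255(img)),
                                     sigma = max(1, kernel / 3)))
  gr <- sobel_gradients(sm)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  nms <- .non_max_suppress(mag, gr$gx, gr$gy)
  strong <- nms & (mag >= high)
  weak <- nms & (mag >= low)
  edges <- .hysteresis(strong, weak)
  structure(list(edges = edges,
                 params_echo = list(low = low, high = high, kernel = kernel)),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %dx%d, %d edge pixels (low=%g high=%g kernel=%d)\n",
              nrow(x$edges), ncol(x$edges), sum(x$edges),
              x$params_echo$low, x$params_echo$high, x$params_echo$kernel))
  invisible(x)
}

.shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Keep pixels that are local maxima of |grad| along the gradient direction,
# quantized to 4 sectors (0, 45, 90, 135 degrees).
.non_max_suppress <- function(mag, gx, gy) {
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  sector <- integer(length(ang))
  sector[(ang < 22.5) | (ang >= 157.5)] <- 0L   # gradient ~horizontal
  sector[ang >= 22.5 & ang < 67.5]   <- 1L      # diagonal down-right
  sector[ang >= 67.5 & ang < 112.5]  <- 2L      # gradient ~vertical
  sector[ang >= 112.5 & ang < 157.5] <- 3L
  dim(sector) <- dim(mag)
  nb <- list(
    list(c(0, 1), c(0, -1)),
    list(c(1, 1), c(-1, -1)),
    list(c(1, 0), c(-1, 0)),
    list(c(1, -1), c(-1, 1)))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    a <- .shift_mat(mag, -nb[[s + 1]][[1]][1], -nb[[s + 1]][[1]][2])
    b <- .shift_mat(mag, -nb[[s + 1]][[2]][1], -nb[[s + 1]][[2]][2])
    keep <- keep | (sector == s & mag >= a & mag > b)
  }
  keep & (mag > 0)
}

# 8-connected hysteresis via a 4-connected labeller: label the 3x3-dilated
# weak-or-strong mask (dilation merges diagonal neighbours into one
# component), keep components that contain a strong pixel.
.hysteresis <- function(strong, weak) {
  mask <- strong | weak
  if (!any(mask)) return(mask)
  eb <- EBImage::Image(t(mask) * 1)
  dil <- EBImage::dilate(eb, EBImage::makeBrush(3, "box"))
  lab <- t(EBImage::imageData(EBImage::bwlabel(dil)))
  keep_labels <- unique(lab[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  mask & (lab %in% keep_labels)
}
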