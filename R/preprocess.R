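#' Median pre-smoothing
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param k Odd window size; `k < 3` is a no-op.
#' @return Filtered image, same size.
#' @export
median_smooth <- function(img, k = 7) {
  validate_gray_image(img)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("median window must be odd")
  if (k < 3L) return(img)
  .from_ebimage(EBImage::medianFilter(.as_ebimage(clip255(img)), k %/% 2L))
}

#' Speckle-aware anisotropic diffusion
#'
#' Perona-Malik diffusion with exponential conduction
#' `g(d) = exp(-(d/kappa)^2)` on the 4-neighbour stencil, reflective
#' (Neumann) boundaries and antisymmetric inter-pixel fluxes, so the global
#' mean is preserved exactly and the scheme is non-negativity preserving for
#' `dt <= 0.25`. Smooths speckle while leaving band edges in place.
#'
#' @param img Grayscale matrix.
#' @param n_iter Number of iterations; 0 returns the input.
#' @param kappa Edge-stopping scale in gray levels.
#' @param dt Time step (stability requires `dt <= 0.25`).
#' @return Diffused image.
#' @export
anisotropic_diffuse <- function(img, n_iter = 15, kappa = 30, dt = 0.2) {
  validate_gray_image(img)
  if (n_iter < 0) stop("n_iter must be >= 0")
  if (dt <= 0 || dt > 0.25) stop("dt must be in (0, 0.25] for stability")
  h <- nrow(img); w <- ncol(img)
  g <- function(d) exp(-(d / kappa)^2)
  for (it in seq_len(n_iter)) {
    dN <- rbind(img[1, , drop = FALSE], img[-h, , drop = FALSE]) - img
    dS <- rbind(img[-1, , drop = FALSE], img[h, , drop = FALSE]) - img
    dW <- cbind(img[, 1, drop = FALSE], img[, -w, drop = FALSE]) - img
    dE <- cbind(img[, -1, drop = FALSE], img[, w, drop = FALSE]) - img
    img <- img + dt * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
  }
  img
}

# Sobel derivatives with replicated borders; gx along columns (x, rightward),
# gy along rows (y, downward).
sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  sh <- function(dr, dc) pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx, gy = gy)
}

#' Dominant edge orientation from a global gradient-orientation histogram
#'
#' Builds a magnitude-weighted histogram of edge orientations (the direction
#' along the edge, perpendicular to the gradient) over `n_bins` bins
#' spanning 180 degrees, and reads the majority direction off as the
#' circular resultant of the histogram in doubled-angle space. Orientations
#' are axial (theta and theta+180 are the same direction), so doubling maps
#' them onto the full circle where the weighted resultant is well defined;
#' it is exact for any slope distribution symmetric about the tilt, which a
#' curved layer band is, whereas the raw histogram mode of such a band sits
#' at the extreme slopes rather than the tilt.
#'
#' @param img Grayscale matrix with non-zero gradient energy.
#' @param n_bins Number of orientation bins (default 36, i.e. 5 degrees).
#' @param return_histogram Attach the orientation histogram as attribute
#'   `histogram` (for diagnostics/plots).
#' @return Tilt angle in degrees in `(-90, 90]`: positive when structures
#'   descend to the right. Rotating the content by the negated angle makes
#'   the dominant edge direction horizontal.
#' @export
estimate_dominant_orientation <- function(img, n_bins = 36,
                                          return_histogram = FALSE) {
  validate_gray_image(img)
  gr <- sobel_gradients(img)
  mag2 <- gr$gx^2 + gr$gy^2  # squared magnitude emphasizes strong edges
  if (sum(mag2) <= 0) stop("no orientation signal")
  phi <- (atan2(gr$gy, gr$gx) * 180 / pi + 90) %% 180  # edge direction [0,180)
  # resultant accumulated from the raw angles (reading it off the binned
  # histogram would bias the estimate by up to half a bin)
  phi2 <- phi * 2 * pi / 180
  sx <- sum(mag2 * cos(phi2)); sy <- sum(mag2 * sin(phi2))
  if (sx^2 + sy^2 < 1e-24) stop("no orientation signal")
  ang <- atan2(sy, sx) * 180 / pi / 2  # back to orientation, (-90, 90]
  if (ang <= -90) ang <- ang + 180
  if (return_histogram) {
    bw <- 180 / n_bins
    bins <- (floor(phi / bw) %% n_bins) + 1L
    hist <- vapply(seq_len(n_bins), function(b) sum(mag2[bins == b]),
                   numeric(1))
    attr(ang, "histogram") <- hist
  }
  ang
}

#' Rotate an image on an expanded canvas
#'
#' Bilinear resampling on a canvas large enough to contain the whole rotated
#' frame, background filled with 0. Positive angles rotate the content
#' clockwise on screen (rows increase downward); the exact point mapping is
#' given by [rotation_transform()].
#'
#' @param img Grayscale matrix.
#' @param angle Degrees, `|angle| <= 90`.
#' @return Rotated image.
#' @export
rotate_image <- function(img, angle) {
  validate_gray_image(img)
  if (abs(angle) > 90) stop("|angle| must be <= 90")
  if (angle == 0) return(img)
  tr <- rotation_transform(angle, dim(img))
  m <- rbind(t(tr$R), tr$off)
  out <- EBImage::affine(.as_ebimage(clip255(img)), m, filter = "bilinear",
                         output.dim = c(tr$dim_out[2], tr$dim_out[1]),
                         bg.col = 0)
  clip255(.from_ebimage(out))
}

#' @rdname rotate_image
#' @details `rotate_to_horizontal()` is the preprocessing entry point: given
#'   the estimated tilt of the layers, call it with `-tilt` to bring them
#'   horizontal.
#' @export
rotate_to_horizontal <- function(img, angle) rotate_image(img, angle)

#' White top-hat enhancement
#'
#' Image minus its morphological opening by a square structuring element:
#' suppresses background plateaus wider than the kernel while retaining the
#' thin bright layer bands and compensating lateral contrast loss.
#'
#' @param img Grayscale matrix.
#' @param kernel_px Odd side of the square structuring element, >= 3.
#' @return Non-negative enhanced image.
#' @export
tophat_enhance <- function(img, kernel_px = 21) {
  validate_gray_image(img)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px %% 2L == 0L || kernel_px < 3L)
    stop("kernel_px must be odd and >= 3")
  if (kernel_px > min(dim(img))) stop("kernel larger than image")
  eb <- .as_ebimage(clip255(img))
  kern <- EBImage::makeBrush(kernel_px, "box")
  pmax(.from_ebimage(EBImage::whiteTopHat(eb, kern)), 0)
}

#' Full preprocessing stage
#'
#' Order: median smoothing, anisotropic diffusion, dominant-orientation
#' estimate, rotation to horizontal (only when the tilt exceeds the
#' dead-band, so already-horizontal scans pass through unrotated), white
#' top-hat enhancement.
#'
#' @param img Grayscale matrix.
#' @param config Pipeline configuration, see [default_config()].
#' @return An `oct_preprocessed` object: `image` (enhanced), `smooth`
#'   (rotated diffused image, before top-hat), `applied_rotation_deg`,
#'   `dim_original`, `dim_rotated` and the `config` echo.
#' @export
preprocess <- function(img, config = default_config()) {
  validate_gray_image(img)
  med <- median_smooth(img, config$median_k)
  dif <- anisotropic_diffuse(med, config$diffusion_iter,
                             config$diffusion_kappa, config$diffusion_dt)
  ang <- tryCatch(estimate_dominant_orientation(dif, config$hog_bins),
                  error = function(e) 0)
  applied <- if (abs(ang) > config$rotation_deadband) ang else 0
  rot <- if (applied != 0) rotate_to_horizontal(dif, -applied) else dif
  enh <- tophat_enhance(rot, config$tophat_kernel)
  structure(list(image = enh, smooth = rot,
                 applied_rotation_deg = applied,
                 dim_original = dim(img), dim_rotated = dim(rot),
                 config = config),
            class = "oct_preprocessed")
}

#' @export
print.oct_preprocessed <- function(x, ...) {
  cat(sprintf("<oct_preprocessed> %dx%d (from %dx%d), rotation %.2f deg\n",
              x$dim_rotated[1], x$dim_rotated[2],
              x$dim_original[1], x$dim_original[2], x$applied_rotation_deg))
  invisible(x)
}
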