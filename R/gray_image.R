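#' Grayscale image utilities
#'
#' Images are plain numeric matrices indexed `[row, col]` with row 1 at the
#' top (rows increase downward, matching raster display) and intensities on
#' the 8-bit scale `[0, 255]`. All pipeline stages consume and produce this
#' representation.
#'
#' @param path Path to an 8-bit grayscale PNG or TIFF file. Color images are
#'   converted by averaging channels.
#' @return A numeric matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(arr)) == 3L) arr <- rowMeans(arr, dims = 2L)
  img <- arr * 255
  validate_gray_image(img)
  img
}

#' @rdname read_gray_image
#' @param img Numeric matrix in `[0, 255]`.
#' @export
write_gray_image <- function(img, path) {
  validate_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(img, 0), 255) / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

validate_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("image must be a non-empty numeric matrix")
  if (any(!is.finite(img)))
    stop("image contains non-finite pixel values")
  invisible(img)
}

# matrix [row, col] <-> EBImage Image (first dim x = col)
.as_ebimage <- function(img) EBImage::Image(t(img) / 255)
.from_ebimage <- function(eb) t(EBImage::imageData(eb)) * 255

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Evaluate f() with a locally seeded RNG stream, restoring global state.
with_local_seed <- function(seed, f) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}
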