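#' Specify a synthetic AS-OCT phantom
#'
#' Phantoms emulate the geometry of anterior-segment OCT scans of an eye
#' wearing a scleral contact lens: a thin bright band for the lens (its top
#' and bottom edges are the lens outer and inner limits), a thicker brighter
#' band for the corneal tissue, a dark background, multiplicative speckle,
#' lateral contrast decay and an optional global tilt. Three scenarios are
#' covered: `central` (lens vaults over the cornea everywhere), `lateral`
#' (clearance closes toward one side) and `extreme` (the lens rests on the
#' tissue; only two boundaries are visible).
#'
#' @param width,height Image size in pixels.
#' @param scenario One of `"central"`, `"lateral"`, `"extreme"`.
#' @param vault Nominal apex clearance between the lens inner limit and the
#'   cornea, in pixels. Forced to 0 for `extreme`; must be > 0 for `central`.
#' @param rotation_deg Global clockwise tilt in degrees, in `[0, 45]`.
#' @param speckle_sigma Log-scale of the mean-one multiplicative speckle.
#' @param contrast_decay Fractional intensity loss per 100 columns away from
#'   the image centre.
#' @param band_intensities Named vector `c(lens=, cornea=, background=)` of
#'   mean gray levels (0-255).
#' @param lens_thickness,cornea_thickness Band thicknesses in pixels.
#' @param cornea_apex_row Apex (topmost) row of the corneal surface.
#'   In the `extreme` scenario the lens has merged optically with the
#'   tissue: a single surface is rendered and all ground-truth curves
#'   coincide at the contact curve.
#' @param cornea_curv Parabolic curvature of the cornea (px row per px col^2).
#' @param gap_curv Growth of the clearance toward the edges for `central`.
#' @param edge_sigma Gaussian edge width of the band profile, in pixels.
#' @param tissue_decay Depth constant (px) of the gradual signal decay below
#'   the corneal surface plateau.
#' @param seed RNG seed; identical specs give bit-identical images.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 300, height = 220,
                         scenario = c("central", "lateral", "extreme"),
                         vault = 25, rotation_deg = 0,
                         speckle_sigma = 0.25, contrast_decay = 0.1,
                         band_intensities = c(lens = 140, cornea = 230,
                                              background = 8),
                         lens_thickness = 7, cornea_thickness = 12,
                         cornea_apex_row = 120, cornea_curv = 2e-3,
                         gap_curv = 6e-4, edge_sigma = 1,
                         tissue_decay = 20, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "extreme") vault <- 0
  spec <- list(width = as.integer(width), height = as.integer(height),
               scenario = scenario, vault = vault,
               rotation_deg = rotation_deg, speckle_sigma = speckle_sigma,
               contrast_decay = contrast_decay,
               band_intensities = band_intensities,
               lens_thickness = lens_thickness,
               cornea_thickness = cornea_thickness,
               cornea_apex_row = cornea_apex_row, cornea_curv = cornea_curv,
               gap_curv = gap_curv, edge_sigma = edge_sigma,
               tissue_decay = tissue_decay, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (width < 40 || height < 40) stop("phantom must be at least 40x40")
    if (vault < 0) stop("vault must be >= 0")
    if (scenario == "central" && vault <= 0)
      stop("central scenario requires vault > 0")
    if (rotation_deg < 0 || rotation_deg > 45)
      stop("rotation_deg must be within [0, 45]")
    if (speckle_sigma < 0) stop("speckle_sigma must be >= 0")
    need <- c("lens", "cornea", "background")
    if (!all(need %in% names(band_intensities)))
      stop("band_intensities needs components: ", paste(need, collapse = ", "))
    top <- cornea_apex_row - vault - lens_thickness
    if (top < 10) stop("lens band would leave the image at the top")
    if (cornea_apex_row + cornea_curv * (width / 2)^2 > height - 5)
      stop("cornea curve leaves the image at the sides")
  })
  invisible(spec)
}

# Analytic boundary rows in the unrotated frame, one value per column.
# In the extreme scenario the lens has merged optically with the tissue, so
# all three boundaries coincide at the contact curve.
phantom_curves <- function(spec) {
  cols <- seq_len(spec$width)
  cx <- (spec$width + 1) / 2
  cornea <- spec$cornea_apex_row + spec$cornea_curv * (cols - cx)^2
  gap <- switch(spec$scenario,
    central = spec$vault + spec$gap_curv * (cols - cx)^2,
    lateral = spec$vault * (spec$width - cols) / (spec$width - 1),
    extreme = rep(0, spec$width))
  inner <- cornea - gap
  outer <- if (spec$scenario == "extreme") cornea
           else inner - spec$lens_thickness
  list(cols = cols, scl_outer = outer, scl_inner = inner, cornea = cornea)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Band with erf-smoothed edges: half-maximum sits exactly on the analytic
# boundary for any thickness, and the vertical-gradient maximum does too.
.band_profile <- function(rowgrid, top, bottom, intensity, sigma) {
  intensity * 0.5 * (erf(outer(rowgrid, top, `-`) / (sqrt(2) * sigma)) -
                     erf(outer(rowgrid, bottom, `-`) / (sqrt(2) * sigma)))
}

# Tissue: sharp erf surface, bright plateau, then gradual exponential signal
# decay with depth (OCT tissue has no sharp lower boundary).
.surface_profile <- function(rowgrid, top, intensity, thickness, sigma,
                             decay_len) {
  depth <- outer(rowgrid, top, `-`)
  intensity * 0.5 * (1 + erf(depth / (sqrt(2) * sigma))) *
    exp(-pmax(depth - thickness, 0) / decay_len)
}

#' Generate a synthetic phantom image with exact ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (8-bit matrix) and `truth`, a `ground_truth`
#'   object holding the analytic boundary curves (in the frame of the emitted,
#'   possibly rotated, image), the visible layer count and the tilt.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  cv <- phantom_curves(spec)
  rows <- seq_len(spec$height)
  img <- matrix(spec$band_intensities[["background"]],
                spec$height, spec$width)
  if (spec$scenario != "extreme")
    img <- img + .band_profile(rows, cv$scl_outer, cv$scl_inner,
                               spec$band_intensities[["lens"]],
                               spec$edge_sigma)
  img <- img + .surface_profile(rows, cv$cornea,
                                spec$band_intensities[["cornea"]],
                                spec$cornea_thickness, spec$edge_sigma,
                                spec$tissue_decay)
  cx <- (spec$width + 1) / 2
  decay <- pmax(0.1, 1 - spec$contrast_decay * abs(cv$cols - cx) / 100)
  img <- sweep(img, 2, decay, `*`)

  two_layer <- spec$scenario == "extreme"
  curves <- list(
    scl_outer = layer_curve(cv$cols, cv$scl_outer),
    scl_inner = if (!two_layer) layer_curve(cv$cols, cv$scl_inner),
    cornea = layer_curve(cv$cols, cv$cornea))
  if (spec$rotation_deg > 0) {
    tr <- rotation_transform(spec$rotation_deg, dim(img))
    img <- rotate_image(img, spec$rotation_deg)
    curves <- lapply(curves, function(cu)
      if (!is.null(cu)) transform_curve(cu, tr, "fwd"))
  }
  if (spec$speckle_sigma > 0) {
    img <- with_local_seed(spec$seed, function() {
      s <- spec$speckle_sigma
      img * exp(matrix(stats::rnorm(length(img), -s^2 / 2, s), nrow(img)))
    })
  }
  img <- round(clip255(img))
  truth <- structure(list(curves = curves,
                          layer_count = if (two_layer) 2L else 3L,
                          scenario = spec$scenario,
                          rotation_deg = spec$rotation_deg,
                          spec = spec),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s scenario, %d layers, tilt %.1f deg\n",
              x$scenario, x$layer_count, x$rotation_deg))
  invisible(x)
}

#' Generate a reproducible batch of phantoms
#'
#' Scenario counts follow the largest-remainder allocation of
#' `n * scenario_mix`; per-item parameters (vault, corneal geometry, band
#' thickness, tilt) are drawn from realistic ranges with an item seed derived
#' deterministically from `base_seed`.
#'
#' @param n Number of phantoms.
#' @param scenario_mix Proportions `c(central, lateral, extreme)`, summing
#'   to 1.
#' @param base_seed Integer seed driving every item.
#' @param speckle_sigma,contrast_decay Noise conditions shared by all items.
#' @param width,height Image size.
#' @return List of `list(image, truth)` pairs.
#' @export
generate_dataset <- function(n, scenario_mix = c(central = 1/3, lateral = 1/3,
                                                 extreme = 1/3),
                             base_seed = 1L, speckle_sigma = 0.25,
                             contrast_decay = 0.1,
                             width = 300, height = 220) {
  if (n < 1) stop("n must be >= 1")
  if (abs(sum(scenario_mix) - 1) > 1e-8)
    stop("scenario_mix must sum to 1")
  scen_names <- c("central", "lateral", "extreme")
  mix <- rep_len(as.numeric(scenario_mix), 3L)
  exact <- n * mix
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  scenarios <- rep(scen_names, counts)
  lapply(seq_len(n), function(i) {
    item_seed <- (as.numeric(base_seed) * 48271 + i * 97) %% 2147483647
    pars <- with_local_seed(item_seed, function() {
      sc <- scenarios[i]
      list(
        vault = if (sc == "extreme") 0 else stats::runif(1, 18, 35),
        cornea_apex_row = stats::runif(1, 0.48, 0.62) * height,
        cornea_curv = 2e-3 * stats::runif(1, 0.7, 1.3),
        lens_thickness = stats::runif(1, 6, 8),
        rotation_deg = switch(sc, central = 0,
                              lateral = stats::runif(1, 8, 35),
                              extreme = stats::runif(1, 10, 40)))
    })
    spec <- phantom_spec(width = width, height = height,
                         scenario = scenarios[i], vault = pars$vault,
                         rotation_deg = pars$rotation_deg,
                         speckle_sigma = speckle_sigma,
                         contrast_decay = contrast_decay,
                         lens_thickness = pars$lens_thickness,
                         cornea_apex_row = pars$cornea_apex_row,
                         cornea_curv = pars$cornea_curv,
                         seed = as.integer(item_seed %% 2147483647))
    generate_phantom(spec)
  })
}

#' Write a phantom's ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    scenario = truth$scenario,
    layer_count = truth$layer_count,
    rotation_deg = truth$rotation_deg,
    curves = lapply(Filter(Negate(is.null), truth$curves), function(cu)
      list(col = cu$cols, row = cu$rows)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
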