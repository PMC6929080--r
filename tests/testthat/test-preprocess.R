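test_that("anisotropic diffusion fixes constant images and preserves the mean", {
  const <- matrix(123, 40, 50)
  expect_equal(anisotropic_diffuse(const, 20), const)
  ph <- generate_phantom(phantom_spec(width = 120, height = 120,
                                      vault = 18, cornea_apex_row = 65,
                                      speckle_sigma = 0.3, seed = 2))
  out <- anisotropic_diffuse(ph$image, 15)
  expect_equal(dim(out), dim(ph$image))
  expect_lt(abs(mean(out) / mean(ph$image) - 1), 0.005)
  expect_identical(anisotropic_diffuse(ph$image, 0), ph$image)
  expect_error(anisotropic_diffuse(matrix(c(1, NA, 3, 4), 2)), "non-finite")
})

test_that("diffusion halves background speckle variance without moving edges", {
  sp <- phantom_spec(width = 160, height = 160, vault = 18,
                     cornea_apex_row = 90, speckle_sigma = 0.3,
                     band_intensities = c(lens = 140, cornea = 230,
                                          background = 40), seed = 6)
  noisy <- generate_phantom(sp)$image
  out <- anisotropic_diffuse(noisy, 15)
  patch <- 10:40  # pure background above the lens
  expect_lt(var(as.vector(out[patch, 30:130])),
            0.5 * var(as.vector(noisy[patch, 30:130])))

  step <- step_image(edge_row = 60, w = 100)
  step <- step + matrix(rnorm(length(step), 0, 5), nrow(step))
  dif <- anisotropic_diffuse(step, 15)
  edge_pos <- vapply(seq(10, 90, 10),
                     function(cc) which.max(diff(dif[, cc])), numeric(1))
  expect_true(all(abs(edge_pos + 0.5 - 59.5) <= 1))
})

test_that("dominant orientation: stripes, tilted phantoms and equivariance", {
  stripes <- matrix(0, 80, 100)
  stripes[seq(10, 70, 12), ] <- 200
  expect_lt(abs(estimate_dominant_orientation(stripes)), 2.5)

  ph30 <- generate_phantom(phantom_spec(scenario = "lateral",
                                        rotation_deg = 30,
                                        speckle_sigma = 0, seed = 4))
  expect_equal(estimate_dominant_orientation(ph30$image), 30, tolerance = 5)

  base <- generate_phantom(phantom_spec(scenario = "lateral",
                                        rotation_deg = 0,
                                        speckle_sigma = 0, seed = 4))
  e0 <- estimate_dominant_orientation(base$image)
  for (delta in c(10, 20, 30)) {
    rot <- rotate_image(base$image, delta)
    expect_equal(estimate_dominant_orientation(rot) - e0, delta,
                 tolerance = 5)
  }
  expect_error(estimate_dominant_orientation(matrix(7, 30, 30)),
               "no orientation signal")
})

test_that("rotation is exact at zero, round-trips, and flattens a tilted phantom", {
  ph <- small_phantom(speckle_sigma = 0, seed = 8)
  expect_identical(rotate_image(ph$image, 0), ph$image)

  fwd <- rotate_image(ph$image, 25)
  back <- rotate_image(fwd, -25)
  # the composed map is a pure translation; sample the round-tripped image
  # at the mapped positions of interior pixels of the original footprint
  tr1 <- rotation_transform(25, dim(ph$image))
  tr2 <- rotation_transform(-25, dim(fwd))
  grid <- as.matrix(expand.grid(row = seq(20, 120, 2), col = seq(20, 140, 2)))
  mapped <- tr2$fwd(tr1$fwd(grid))
  vals <- bilinear_at(back, mapped[, 1], mapped[, 2])
  expect_lt(mean(abs(vals - ph$image[grid])), 2)

  ph30 <- generate_phantom(phantom_spec(scenario = "lateral",
                                        rotation_deg = 30,
                                        speckle_sigma = 0, seed = 5))
  flat <- rotate_to_horizontal(ph30$image, -30)
  expect_lt(abs(structure_tensor_orientation(flat)), 5)
})

test_that("rotation transform maps points exactly both ways", {
  tr <- rotation_transform(37, c(100, 140))
  pts <- cbind(c(10, 50, 99.5), c(20, 70, 139.5))
  there <- tr$fwd(pts)
  back <- tr$inv(there)
  expect_equal(back, pts, tolerance = 1e-10)
})

test_that("white top-hat suppresses plateaus and keeps thin bands", {
  expect_true(all(tophat_enhance(matrix(120, 60, 60), 21) == 0))

  img <- matrix(5, 80, 80)
  img[40:42, ] <- 205  # 3-px band
  th <- tophat_enhance(img, 21)
  expect_gt(mean(th[41, ]), 150)
  expect_true(all(th >= 0))
  expect_error(tophat_enhance(matrix(0, 10, 10), 21), "larger than image")
  expect_error(tophat_enhance(matrix(0, 50, 50), 4), "odd")

  # lateral contrast decay: band/background contrast at the image edge
  # improves relative to the raw image
  sp <- phantom_spec(width = 200, height = 120, vault = 18,
                     cornea_apex_row = 65, contrast_decay = 0.25,
                     speckle_sigma = 0, seed = 1)
  ph <- generate_phantom(sp)
  th2 <- tophat_enhance(ph$image, 21)
  cu <- ph$truth$curves$scl_inner
  r <- round(cu$rows[match(10, cu$cols)]) - 3  # inside lens band at edge col
  contrast <- function(im) im[r, 10] / max(mean(im[10:30, 1:20]), 1)
  expect_gt(contrast(th2), contrast(ph$image))
})

test_that("median smoothing removes impulses and is idempotent on constants", {
  const <- matrix(55, 40, 40)
  expect_equal(median_smooth(const, 7), const)
  img <- matrix(100, 60, 60)
  img[30, 30] <- 255
  out <- median_smooth(img, 7)
  expect_equal(out[30, 30], 100)
  # salt-and-pepper corruption mostly restored
  set.seed(2)
  base <- small_phantom(seed = 3)$image
  mask <- matrix(runif(length(base)) < 0.03, nrow(base))
  corrupted <- base
  corrupted[mask] <- ifelse(runif(sum(mask)) < 0.5, 0, 255)
  rest <- median_smooth(corrupted, 7)
  expect_gt(mean(abs(rest[mask] - base[mask]) <= 10), 0.9)
})

test_that("preprocess composes the stages and records the applied rotation", {
  cfg <- default_config()
  ph <- generate_phantom(phantom_spec(speckle_sigma = 0.2, seed = 10))
  pre <- preprocess(ph$image, cfg)
  expect_equal(pre$applied_rotation_deg, 0, tolerance = 5)
  expect_identical(pre$dim_original, dim(ph$image))

  ph35 <- generate_phantom(phantom_spec(scenario = "lateral",
                                        rotation_deg = 35,
                                        speckle_sigma = 0.2, seed = 11))
  pre35 <- preprocess(ph35$image, cfg)
  expect_gt(abs(pre35$applied_rotation_deg), 25)
  expect_lt(abs(structure_tensor_orientation(pre35$smooth)), 5)

  expect_identical(preprocess(ph$image, cfg)$image, pre$image)
})
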