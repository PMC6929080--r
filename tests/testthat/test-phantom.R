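test_that("noiseless flat-band construction places plateaus at the analytic rows", {
  # near-flat bands: curvature ~0 so boundaries sit at constant rows
  sp <- phantom_spec(width = 120, height = 200, scenario = "central",
                     vault = 50, speckle_sigma = 0, contrast_decay = 0,
                     cornea_apex_row = 160, cornea_curv = 1e-9,
                     gap_curv = 0, lens_thickness = 10, seed = 1)
  ph <- generate_phantom(sp)
  rm <- rowMeans(ph$image)
  # lens band between rows 100 and 110, cornea surface at 160
  expect_gt(mean(rm[103:107]), 100)       # lens plateau
  expect_lt(max(rm[1:95]), 15)            # background above
  expect_lt(max(rm[115:150]), 15)         # gap between lens and cornea
  expect_gt(mean(rm[162:170]), 180)       # cornea plateau
  expect_equal(min(ph$truth$curves$scl_outer$rows), 100, tolerance = 1e-6)
  expect_equal(min(ph$truth$curves$cornea$rows), 160, tolerance = 1e-6)
})

test_that("same spec and seed give bit-identical images", {
  sp <- phantom_spec(speckle_sigma = 0.3, seed = 77)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  sp2 <- phantom_spec(speckle_sigma = 0.3, seed = 78)
  expect_false(identical(generate_phantom(sp2)$image, a$image))
})

test_that("rotated phantom has the requested dominant orientation (structure-tensor oracle)", {
  ph <- generate_phantom(phantom_spec(scenario = "lateral",
                                      rotation_deg = 30,
                                      speckle_sigma = 0, seed = 3))
  expect_equal(structure_tensor_orientation(ph$image), 30, tolerance = 5)
})

test_that("per-column gradient argmax recovers every ground-truth boundary within 1 px", {
  for (sc in c("central", "lateral", "extreme")) {
    ph <- generate_phantom(phantom_spec(scenario = sc, speckle_sigma = 0,
                                        seed = 9))
    img <- ph$image
    for (nm in c("scl_outer", "scl_inner", "cornea")) {
      cu <- ph$truth$curves[[nm]]
      if (is.null(cu)) next
      cols <- cu$cols[seq(5, length(cu$cols) - 5, by = 7)]
      err <- vapply(cols, function(cc) {
        r <- cu$rows[match(cc, cu$cols)]
        win <- max(1, floor(r - 3)):min(nrow(img) - 1, ceiling(r + 3))
        g <- diff(img[, cc])[win]
        # limit tops are rises; the lens inner limit is a falling edge
        pick <- if (nm == "scl_inner") which.min(g) else which.max(g)
        (win[pick] + 0.5) - r
      }, numeric(1))
      expect_lt(max(abs(err)), 1)
    }
  }
})

test_that("speckle is multiplicative with mean one (200-seed average)", {
  sp0 <- phantom_spec(width = 100, height = 120, scenario = "central",
                      vault = 18, cornea_apex_row = 65, speckle_sigma = 0,
                      contrast_decay = 0, seed = 1)
  clean <- generate_phantom(sp0)$image
  acc <- matrix(0, nrow(clean), ncol(clean))
  for (s in 1:200) {
    sp <- phantom_spec(width = 100, height = 120, scenario = "central",
                       vault = 18, cornea_apex_row = 65,
                       speckle_sigma = 0.25, contrast_decay = 0, seed = s)
    acc <- acc + generate_phantom(sp)$image
  }
  avg <- acc / 200
  # judge on mid-intensity pixels where 8-bit clipping is negligible
  sel <- clean > 50 & clean < 160
  expect_gt(sum(sel), 500)
  expect_lt(abs(mean(avg[sel]) / mean(clean[sel]) - 1), 0.02)
})

test_that("dataset generation honors counts, mix and reproducibility", {
  ds <- generate_dataset(6, base_seed = 5, width = 120, height = 120)
  scen <- vapply(ds, function(x) x$truth$scenario, character(1))
  expect_equal(as.vector(table(factor(scen,
    levels = c("central", "lateral", "extreme")))), c(2, 2, 2))

  one <- generate_dataset(1, scenario_mix = c(1, 0, 0), base_seed = 2,
                          width = 120, height = 120)
  expect_equal(one[[1]]$truth$scenario, "central")
  expect_equal(one[[1]]$truth$layer_count, 3L)

  a <- generate_dataset(8, base_seed = 11, width = 120, height = 120)
  b <- generate_dataset(8, base_seed = 11, width = 120, height = 120)
  for (i in seq_along(a)) expect_identical(a[[i]]$image, b[[i]]$image)
})

test_that("invalid specifications are rejected", {
  expect_error(phantom_spec(scenario = "central", vault = 0), "vault")
  expect_error(phantom_spec(rotation_deg = 60), "rotation")
  expect_error(phantom_spec(vault = -3), "vault")
  expect_error(generate_dataset(0), "n must be")
  expect_error(generate_dataset(4, scenario_mix = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("ground truth export writes valid JSON", {
  ph <- small_phantom()
  f <- tempfile(fileext = ".json")
  write_ground_truth(ph$truth, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$scenario, "central")
  expect_equal(gt$layer_count, 3)
  expect_equal(length(gt$curves$cornea$col), length(ph$truth$curves$cornea$cols))
  unlink(f)
})
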