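test_that("Canny finds no edges on constants and stays near true boundaries", {
  em <- detect_edges(matrix(80, 50, 50))
  expect_equal(sum(em$edges), 0)

  ph <- small_phantom(seed = 12)
  em2 <- detect_edges(ph$image, 90, 120, 3)
  cu <- ph$truth$curves$cornea
  hits <- vapply(seq(10, 150, 5), function(cc) {
    r <- round(cu$rows[match(cc, cu$cols)])
    any(em2$edges[max(1, r - 2):min(nrow(ph$image), r + 2), cc])
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("raising Canny thresholds never adds edge pixels", {
  ph <- small_phantom(speckle_sigma = 0.25, seed = 13)
  prev <- detect_edges(ph$image, 30, 60)$edges
  for (sh in c(30, 60, 90)) {
    cur <- detect_edges(ph$image, 30 + sh, 60 + sh)$edges
    expect_true(all(prev[cur]))  # cur subset of prev
    prev <- cur
  }
})

test_that("row edge profile counts per-row pixels and conserves the total", {
  E <- matrix(FALSE, 80, 120)
  E[40, 11:110] <- TRUE
  prof <- row_edge_profile(E)
  expect_length(prof, 80)
  expect_equal(prof[40], 100)
  expect_equal(sum(prof[-40]), 0)
  expect_equal(sum(row_edge_profile(matrix(FALSE, 10, 10))), 0)
  ph <- small_phantom(seed = 1)
  em <- detect_edges(ph$image)
  expect_equal(sum(row_edge_profile(em)), sum(em$edges))
})

test_that("initial searching rows: constructed rises, extremes, first-three rule", {
  prof <- rep(2, 200)
  prof[50:55] <- 60; prof[100:104] <- 55; prof[160:163] <- 50
  rows <- find_initial_rows(prof, threshold = 20)
  expect_length(rows, 3)
  expect_true(all(abs(rows - c(50, 100, 160)) <= 2))

  prof2 <- rep(1, 150); prof2[30:34] <- 40; prof2[90:94] <- 45
  expect_length(find_initial_rows(prof2, threshold = 15), 2)

  prof5 <- rep(0, 300)
  for (r in c(40, 80, 120, 160, 200)) prof5[r:(r + 3)] <- 50
  rows5 <- find_initial_rows(prof5, threshold = 20)
  expect_length(rows5, 3)
  expect_true(all(abs(rows5 - c(40, 80, 120)) <= 2))

  expect_length(find_initial_rows(rep(3, 100), threshold = 50), 0)
  expect_error(find_initial_rows(c(1, 2)), "too short")
})

test_that("cornea searching row wins by intensity variation and is brightness-stable", {
  ph <- small_phantom(seed = 14)
  tcur <- ph$truth$curves
  cand <- round(c(min(tcur$scl_outer$rows), min(tcur$scl_inner$rows),
                  min(tcur$cornea$rows)))
  lab <- identify_cornea_row(ph$image, cand)
  expect_equal(lab$cornea, cand[3])
  expect_equal(lab$scl_outer, cand[1])
  expect_equal(lab$scl_inner, cand[2])

  # extreme: two candidates, the lower (tissue) one is the cornea
  phe <- small_phantom("extreme", seed = 14)
  ce <- round(min(phe$truth$curves$cornea$rows))
  labe <- identify_cornea_row(phe$image, c(ce - 40, ce))
  expect_equal(labe$cornea, ce)
  expect_equal(labe$scl_outer, ce - 40)

  # doubling the cornea band brightness never flips the labeling
  bright <- generate_phantom(phantom_spec(
    width = 160, height = 140, vault = 18, cornea_apex_row = 75,
    speckle_sigma = 0, seed = 14,
    band_intensities = c(lens = 115, cornea = 230, background = 8)))
  lab2 <- identify_cornea_row(bright$image, cand)
  expect_equal(lab2$cornea, lab$cornea)
})

test_that("tracing bridges gaps with interpolation and rejects off-curve noise", {
  E <- matrix(FALSE, 90, 120)
  E[40, 10:100] <- TRUE
  E[40, 50:54] <- FALSE           # 5-column gap
  img <- matrix(0, 90, 120); img[38:42, ] <- 200
  cu <- trace_limit(E, img, start = c(40, 20))
  expect_true(all(cu$provenance[match(50:54, cu$cols)] == "interpolated"))
  expect_equal(cu$rows[match(50:54, cu$cols)], rep(40, 5), tolerance = 1e-6)
  expect_true(all(abs(cu$rows - 40) < 0.5))

  # isolated bright noise pixel 6 rows off the curve is not followed
  E2 <- E; E2[46, 60] <- TRUE
  img2 <- img; img2[46, 60] <- 255
  cu2 <- trace_limit(E2, img2, start = c(40, 20))
  expect_lt(abs(cu2$rows[match(60, cu2$cols)] - 40), 1)

  expect_error(trace_limit(E, img, start = c(10, 10)), "not on an edge")
})

test_that("tracing a noiseless phantom outer limit stays within 1 px of truth", {
  ph <- small_phantom(seed = 15)
  cfg <- default_config()
  pre <- preprocess(ph$image, cfg)
  em <- detect_edges(pre$image, cfg$canny_low, cfg$canny_high)
  truth <- ph$truth$curves$scl_outer
  r0 <- round(min(truth$rows))
  seedp <- which(em$edges[(r0):(r0 + 8), , drop = FALSE], arr.ind = TRUE)[1, ]
  cu <- trace_limit(em, pre$image, c(r0 + seedp[1] - 1, seedp[2]))
  err <- curve_error(cu, truth)
  expect_lte(err["mae"], 1)
})

test_that("inner limit follows the band width and never rises above the outer", {
  img <- matrix(8, 100, 80)
  img[50:59, ] <- 200  # constant 10-px band starting at row 50
  outer <- layer_curve(1:80, rep(49.5, 80))
  inner <- find_inner_limit(img, outer, grad_thresh = 10)
  widths <- inner$rows - outer$rows
  expect_gt(mean(abs(widths - 10) <= 1), 0.95)
  expect_true(all(inner$rows >= outer$rows))

  # a column without contrast reuses the neighbouring width
  img2 <- img; img2[, 40] <- 8
  inner2 <- find_inner_limit(img2, outer, grad_thresh = 10)
  expect_equal(inner2$provenance[40], "extrapolated")
  expect_lt(abs((inner2$rows[40] - outer$rows[40]) - 10), 1.5)
})

test_that("preliminary localization classifies scenarios and keeps curve order", {
  cfg <- default_config()
  loc_c <- preliminary_localization(small_phantom(seed = 16)$image, cfg)
  expect_equal(loc_c$region_class, "three_layers")
  expect_false(is.null(loc_c$scl_inner))

  loc_e <- preliminary_localization(small_phantom("extreme", seed = 16)$image,
                                    cfg)
  expect_equal(loc_e$region_class, "two_layers")
  expect_null(loc_e$scl_inner)

  expect_error(preliminary_localization(matrix(40, 120, 120), cfg),
               "no layers")

  # non-crossing invariant over a batch of random noisy phantoms
  ds <- generate_dataset(12, base_seed = 31, width = 200, height = 180)
  for (it in ds) {
    ls <- tryCatch(preliminary_localization(it$image, cfg),
                   error = function(e) NULL)
    if (is.null(ls)) next
    sh <- intersect(ls$scl_outer$cols, ls$cornea$cols)
    expect_true(all(curve_row_at(ls$scl_outer, sh) <=
                      curve_row_at(ls$cornea, sh) + 1e-9))
    if (!is.null(ls$scl_inner)) {
      sh2 <- intersect(ls$scl_inner$cols, sh)
      expect_true(all(curve_row_at(ls$scl_outer, sh2) <=
                        curve_row_at(ls$scl_inner, sh2) + 1e-9))
      expect_true(all(curve_row_at(ls$scl_inner, sh2) <=
                        curve_row_at(ls$cornea, sh2) + 1e-9))
    }
  }
})
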