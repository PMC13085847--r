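test_that("spatial contrast: constant frame, checkerboard enumeration, scale invariance", {
  const <- matrix(7, 20, 20)
  k <- spatial_contrast(const, 3)$contrast
  expect_true(all(k == 0))
  # checkerboard of {0, 2}: oracle is direct enumeration of the 9-pixel
  # window (population sd / window mean). A 3x3 window holds a 5/4 or 4/5
  # split depending on the center pixel, giving sqrt(5)/2 or 2/sqrt(5).
  cb <- outer(1:21, 1:21, function(i, j) ((i + j) %% 2) * 2)
  k <- spatial_contrast(cb, 3)$contrast[, , 1]
  interior <- k[2:20, 2:20]
  w1 <- c(0, 2, 0, 2, 0, 2, 0, 2, 0) # enumeration oracle, center = 0
  w2 <- c(2, 0, 2, 0, 2, 0, 2, 0, 2) # center = 2
  pop_cv <- function(v) sqrt(mean((v - mean(v))^2)) / mean(v)
  expect_true(all(abs(interior - pop_cv(w1)) < 1e-9 |
                  abs(interior - pop_cv(w2)) < 1e-9))
  expect_equal(max(interior), pop_cv(w1), tolerance = 1e-9) # sqrt(5)/2
  expect_equal(min(interior), pop_cv(w2), tolerance = 1e-9) # 2/sqrt(5)
  # scaling all intensities leaves K unchanged
  img <- matrix(stats::runif(400, 1, 2), 20, 20)
  expect_equal(spatial_contrast(img, 5)$contrast,
               spatial_contrast(img * 37.5, 5)$contrast, tolerance = 1e-12)
  # zero local mean marked invalid
  z <- matrix(0, 10, 10); z[9, 9] <- 1
  k0 <- spatial_contrast(z, 3)$contrast[, , 1]
  expect_true(is.na(k0[1, 1]))
  expect_error(spatial_contrast(const, 4), "odd")
  expect_error(spatial_contrast(const, 21), "smaller")
})

test_that("baseline map averages the requested frames", {
  arr <- array(0, c(4, 4, 10))
  for (t in 1:10) arr[, , t] <- if (t %% 2) 100 else 300
  series <- structure(list(ict = arr, beta = 1, exposure = 5e-3,
                           n_clamped = 0L), class = "ict_series")
  expect_true(all(baseline_map(series, 1, 10) == 200))
  expect_true(all(baseline_map(series, 2, 1) == 300))
  sameframes <- series; sameframes$ict[] <- 42
  expect_true(all(baseline_map(sameframes, 1, 10) == 42))
  expect_error(baseline_map(series, 5, 10), "outside")
})

test_that("relative CBF and epoch means follow the ratio arithmetic", {
  arr <- array(200, c(6, 6, 6))
  arr[, , 4:6] <- 100
  series <- structure(list(ict = arr, beta = 1, exposure = 5e-3,
                           n_clamped = 0L), class = "ict_series")
  base <- baseline_map(series, 1, 3)
  rr <- relative_cbf_series(series, base)
  expect_true(all(rr$ratio[, , 1:3] == 1))
  expect_true(all(rr$ratio[, , 4:6] == 0.5))
  # epoch mean of constant 0.5 -> -50 percent
  d <- epoch_mean_change(rr, c(4, 6))
  expect_true(all(d$percent_change == -50))
  expect_true(all(epoch_mean_change(rr, c(1, 3))$percent_change == 0))
  # alternating 0.4 / 0.6 averages to -50
  arr2 <- array(200, c(4, 4, 4))
  arr2[, , 3] <- 80; arr2[, , 4] <- 120
  s2 <- structure(list(ict = arr2, beta = 1, exposure = 5e-3, n_clamped = 0L),
                  class = "ict_series")
  r2 <- relative_cbf_series(s2, baseline_map(s2, 1, 2))
  expect_true(all(abs(epoch_mean_change(r2, 3:4)$percent_change + 50) < 1e-9))
  # zero baseline pixels become invalid
  base0 <- base; base0[1, 1] <- 0
  r0 <- relative_cbf_series(series, base0)
  expect_true(all(is.na(r0$ratio[1, 1, ])))
  expect_error(relative_cbf_series(series, base[1:3, 1:3]), "shape")
  expect_error(epoch_mean_change(rr, integer(0)), "empty")
})

test_that("pseudocolor map obeys the clipping and neutral-midpoint contract", {
  z <- matrix(0, 5, 5)
  rgbz <- pseudocolor_map(structure(list(percent_change = z), class = "delta_cbf_map"))
  for (ch in 1:3) {
    expect_true(all(abs(rgbz[, , ch] - rgbz[1, 1, ch]) < 1e-12))
  }
  m <- matrix(c(-100, 100, -150, 0), 2, 2)
  r1 <- pseudocolor_map(m, clip = 100)
  # -150 clipped to the same color as -100
  expect_equal(r1[1, 1, ], r1[1, 2, ])
  # extremes differ from each other and from neutral
  expect_false(isTRUE(all.equal(r1[1, 1, ], r1[2, 1, ])))
  # invalid pixels render the distinct gray
  mna <- matrix(NA_real_, 2, 2)
  expect_true(all(pseudocolor_map(mna) == 0.25))
  expect_error(pseudocolor_map(m, clip = 0), "clip")
})

test_that("ROI statistics: hand-checked mean/SE, duplicates, invalid handling", {
  m <- matrix(-70, 10, 10)
  roi <- matrix(TRUE, 10, 10)
  r <- roi_mean_change(m, list(core = roi))
  expect_equal(r$mean, -70)
  expect_equal(r$se, 0)
  # two pixels {-60, -80}: mean -70, SE = sd/sqrt(2) = 10 (hand arithmetic)
  m2 <- matrix(0, 2, 2); m2[1, 1] <- -60; m2[2, 1] <- -80
  mask2 <- matrix(FALSE, 2, 2); mask2[, 1] <- TRUE
  r2 <- roi_mean_change(m2, list(pair = mask2))
  expect_equal(r2$mean, -70)
  expect_equal(r2$se, 10)
  # duplicate masks give identical rows
  r3 <- roi_mean_change(m2, list(a = mask2, b = mask2))
  expect_equal(r3$mean[1], r3$mean[2])
  expect_equal(r3$se[1], r3$se[2])
  # fully invalid ROI is flagged, not silently zero
  mna <- matrix(NA_real_, 2, 2)
  expect_warning(rna <- roi_mean_change(mna, list(bad = mask2)), "valid")
  expect_true(rna$all_invalid)
  expect_error(roi_mean_change(m2, list(empty = matrix(FALSE, 2, 2))), "empty")
})

test_that("end-to-end: 70 percent flow drop in the core ROI is recovered", {
  size <- 110
  core <- matrix(FALSE, size, size)
  core[30:75, 30:75] <- TRUE
  sc <- flow_scene(matrix(200, size, size),
                   epochs = data.frame(start = 11, end = 14, factor = 0.3),
                   region = core)
  st <- gen_speckle_stack(sc, 5e-3, 1, n_frames = 14, seed = 21, window = 7)
  ict <- suppressWarnings(contrast_to_ict(spatial_contrast(st, 7)))
  base <- baseline_map(ict, 1, 10)
  rr <- relative_cbf_series(ict, base)
  d <- epoch_mean_change(rr, c(11, 14))
  roi_core <- matrix(FALSE, size, size); roi_core[36:69, 36:69] <- TRUE
  roi_out <- matrix(FALSE, size, size); roi_out[10:22, 10:95] <- TRUE
  res <- roi_mean_change(d, list(core = roi_core, outside = roi_out))
  expect_gt(res$n_valid[1], 500)
  expect_lt(abs(res$mean[1] - (-70)), 5)
  # outside the occluded region flow is unchanged
  expect_lt(abs(res$mean[2]), 3)
  # baseline self-test: epoch over the baseline frames is ~0
  d0 <- epoch_mean_change(rr, c(1, 10))
  expect_lt(max(abs(d0$percent_change), na.rm = TRUE), 3)
})
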