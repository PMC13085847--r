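test_that("measurement region: ring 0 equals mask, dilation grows, components preserved", {
  img <- tube_image(diameter = 6)
  mask <- segment_vessels(img, 0.5)
  r0 <- perivascular_region(mask, ring_width_um = 0)
  expect_identical(r0$region, mask$mask)
  r2 <- perivascular_region(mask, ring_width_um = 2)
  expect_gt(sum(r2$region), sum(mask$mask))
  expect_true(all(r2$region[mask$mask]))
  # background excludes the guard margin around vessels
  expect_false(any(r2$background & r2$region))
  # disjoint tubes keep separate region components when the ring is small
  img2 <- pmax(tube_image(diameter = 5, y_um = 15),
               tube_image(diameter = 5, y_um = 45))
  m2 <- segment_vessels(img2, 0.5)
  rr <- perivascular_region(m2, ring_width_um = 2)
  lab <- EBImage::bwlabel(EBImage::Image(rr$region * 1))
  expect_equal(max(as.matrix(EBImage::imageData(lab))), 2)
  expect_error(perivascular_region(mask, ring_width_um = -1), "ring_width")
})

test_that("intensity fold: arithmetic, polarity, illumination invariance", {
  bf <- matrix(40, 20, 20)
  region <- matrix(FALSE, 20, 20); region[5:8, ] <- TRUE
  backgr <- matrix(FALSE, 20, 20); backgr[15:20, ] <- TRUE
  bf[region] <- 80
  r <- intensity_fold(bf, region, backgr, "increase")
  expect_equal(r$fold, 2)
  expect_equal(r$region_mean, 80)
  expect_equal(r$background_mean, 40)
  # decrease polarity inverts the ratio convention
  rd <- intensity_fold(bf, region, backgr, "decrease")
  expect_equal(rd$fold, 0.5)
  # uniform image -> fold 1
  expect_equal(intensity_fold(matrix(3, 20, 20), region, backgr)$fold, 1)
  # global illumination scaling leaves the fold unchanged
  r2 <- intensity_fold(bf * 2, region, backgr, "increase")
  expect_equal(r2$fold, r$fold)
  expect_error(intensity_fold(matrix(0, 20, 20), region, backgr), "zero")
  expect_error(intensity_fold(bf, region, region), "disjoint")
})

test_that("generator truth is recovered exactly at zero noise", {
  for (fold in c(1, 4)) {
    sc <- gen_histology_scene(stain_fold = fold, seed = 3, noise_sd = 0)
    mask <- strokeflow:::new_vessel_mask(sc$truth$vessel_mask, 0.5)
    reg <- perivascular_region(mask, 0)
    r <- intensity_fold(sc$image[, , 2], reg$region, reg$background,
                        "increase")
    expect_equal(r$fold, fold, tolerance = 1e-12)
  }
  # decrease polarity scene measures back the same fold
  scd <- gen_histology_scene(4, polarity = "decrease", seed = 3)
  maskd <- strokeflow:::new_vessel_mask(scd$truth$vessel_mask, 0.5)
  regd <- perivascular_region(maskd, 0)
  expect_equal(intensity_fold(scd$image[, , 2], regd$region, regd$background,
                              "decrease")$fold, 4, tolerance = 1e-12)
  expect_error(gen_histology_scene(0), "stain_fold")
})

test_that("measured fold is monotone in the planted fold and robust to 5 percent noise", {
  measured <- vapply(c(0.5, 1, 2, 4), function(f) {
    sc <- gen_histology_scene(f, seed = 17, noise_sd = 0)
    mask <- strokeflow:::new_vessel_mask(sc$truth$vessel_mask, 0.5)
    reg <- perivascular_region(mask, 0)
    intensity_fold(sc$image[, , 2], reg$region, reg$background)$fold
  }, 0)
  expect_true(all(diff(measured) > 0))
  # recovery within 10 percent across folds and seeds at 5 percent noise
  for (f in c(0.5, 1, 2, 4)) {
    for (s in 1:5) {
      sc <- gen_histology_scene(f, seed = 20 + s, noise_sd = 0.05)
      mask <- strokeflow:::new_vessel_mask(sc$truth$vessel_mask, 0.5)
      reg <- perivascular_region(mask, 0)
      m <- intensity_fold(sc$image[, , 2], reg$region, reg$background)$fold
      expect_lt(abs(m - f) / f, 0.10)
    }
  }
})

test_that("semi-quantitative binning: nearest multiple, half-up, clamped", {
  expect_equal(semiquant_scale(4.3, 6, 1), 4)
  expect_equal(semiquant_scale(4.5, 6, 1), 5) # half rounds up
  expect_equal(semiquant_scale(0.45, 1, 0.2), 0.4)
  expect_equal(semiquant_scale(0.51, 1, 0.2), 0.6)
  expect_equal(semiquant_scale(9.0, 6, 1), 6)  # clamped to the scale top
  expect_equal(semiquant_scale(0.04, 1, 0.2), 0)
  expect_error(semiquant_scale(-1, 6, 1), "non-negative")
  expect_error(semiquant_scale(1, 6, 0), "step")
  expect_error(semiquant_scale(1, 6.5, 1), "multiple")
})
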