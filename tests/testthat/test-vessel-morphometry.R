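test_that("segmentation: blank, tube area, idempotence, saturation", {
  blank <- matrix(0, 50, 50)
  m <- segment_vessels(blank, 0.5)
  expect_false(any(m$mask))
  # noiseless 6-um tube: mask area within 15 percent of length x diameter
  img <- tube_image(diameter = 6)
  m6 <- segment_vessels(img, 0.5)
  area_um2 <- sum(m6$mask) * 0.5^2
  expect_lt(abs(area_um2 - 100 * 6) / (100 * 6), 0.15)
  # segmenting the mask itself returns the mask
  m_again <- segment_vessels(m6$mask * 1, 0.5)
  expect_identical(m_again$mask, m6$mask)
  expect_error(segment_vessels(matrix(5, 10, 10), 0.5), "saturated")
  expect_error(segment_vessels(blank, -1), "pixel_size")
})

test_that("vessel graph: diameters, Y topology, disjoint components", {
  # straight 4-um tube: median measured diameter within 0.5 um
  g4 <- build_vessel_graph(segment_vessels(tube_image(diameter = 4), 0.5))
  d4 <- unlist(lapply(g4$edges, function(e) e$diameter_um))
  expect_lt(abs(stats::median(d4) - 4), 0.5)
  # diameter estimator bias <= max(0.5 um, 1 px) on 3-12 um tubes
  for (D in c(3, 6, 9, 12)) {
    g <- build_vessel_graph(segment_vessels(tube_image(diameter = D), 0.5))
    d <- unlist(lapply(g$edges, function(e) e$diameter_um))
    expect_lt(abs(stats::median(d) - D), 0.5)
  }
  # Y-shaped mask: one junction, three endpoints
  gy <- build_vessel_graph(segment_vessels(y_tube_image(), 0.5))
  expect_equal(sum(gy$nodes$type == "junction"), 1)
  expect_equal(sum(gy$nodes$type == "endpoint"), 3)
  # two disjoint tubes -> two components
  img2 <- tube_image(diameter = 5, y_um = 20)
  img2 <- pmax(img2, tube_image(diameter = 5, y_um = 45))
  g2 <- build_vessel_graph(segment_vessels(img2, 0.5))
  expect_equal(strokeflow:::graph_components(g2), 2)
  # single-pixel mask: empty graph with warning
  single <- matrix(FALSE, 20, 20); single[10, 10] <- TRUE
  expect_warning(g1 <- build_vessel_graph(single, 0.5), "structure")
  expect_equal(length(g1$edges), 0)
  expect_error(build_vessel_graph(matrix(FALSE, 5, 5), 0.5), "empty")
})

test_that("constriction rule: threshold, capillary cutoff, merging", {
  # 6-um tube with a focal dip to ~4.2 um (30 percent)
  sc <- gen_vessel_scene(n_vessels = 1, constriction_spec = 0.30,
                         pixel_size = 0.4, noise_sd = 0, seed = 7,
                         baseline_diameters = 6)
  m <- segment_vessels(sc$image[, , 1], 0.4, supersample = 2)
  ev <- detect_constrictions(build_vessel_graph(m))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$narrowing - 0.30), 0.06)
  expect_lt(abs(ev$x_um - sc$truth$constrictions$x_um), 5)
  # 15 percent dip: below the 20 percent threshold, no event
  sc15 <- gen_vessel_scene(1, 0.15, pixel_size = 0.4, noise_sd = 0, seed = 7,
                           baseline_diameters = 6)
  m15 <- segment_vessels(sc15$image[, , 1], 0.4, supersample = 2)
  expect_equal(nrow(detect_constrictions(build_vessel_graph(m15))), 0)
  # 12-um vessel with a 30 percent dip: excluded by the 9-um capillary rule
  sc12 <- gen_vessel_scene(1, 0.30, pixel_size = 0.4, noise_sd = 0, seed = 7,
                           baseline_diameters = 12)
  m12 <- segment_vessels(sc12$image[, , 1], 0.4, supersample = 2)
  expect_equal(nrow(detect_constrictions(build_vessel_graph(m12))), 0)
  # empty spec -> empty truth and no events
  sc0 <- gen_vessel_scene(1, numeric(0), pixel_size = 0.4, seed = 7)
  expect_equal(nrow(sc0$truth$constrictions), 0)
  expect_error(detect_constrictions(build_vessel_graph(
    segment_vessels(sc0$image[, , 1], 0.4)), narrowing_threshold = 1.2),
    "narrowing_threshold")
})

test_that("soma detection and association rules", {
  sc <- gen_vessel_scene(n_vessels = 2, constriction_spec = c(0.3, 0.3),
                         n_somata = 3, pixel_size = 0.5, noise_sd = 0,
                         seed = 13)
  expect_equal(nrow(sc$truth$somata), 3)
  som <- detect_somata(sc$image[, , 2], 0.5)
  expect_equal(nrow(som), 3)
  # centroids within 1 um of the planted truth
  for (i in seq_len(3)) {
    d <- sqrt((som$x_um - sc$truth$somata$x_um[i])^2 +
              (som$y_um - sc$truth$somata$y_um[i])^2)
    expect_lt(min(d), 1)
  }
  # empty channel -> empty list
  expect_equal(nrow(detect_somata(matrix(0, 30, 30), 0.5)), 0)
  # blob larger than max_diameter is excluded
  big <- strokeflow:::render_blob(matrix(0, 80, 80), c(20, 20), 20, 0.5)
  expect_equal(nrow(detect_somata(big, 0.5, max_diameter = 15)), 0)
  expect_equal(nrow(detect_somata(big, 0.5, max_diameter = 30)), 1)
  # association: < 10 um associates, >= 10 um does not
  ev <- data.frame(x_um = 0, y_um = 0, local_diameter = 4,
                   reference_diameter = 6, narrowing = 0.33, edge = 1L)
  near <- associate_constrictions(ev, data.frame(x_um = 8, y_um = 0))
  expect_true(near$pericyte_associated)
  expect_equal(near$soma_distance, 8)
  far <- associate_constrictions(ev, data.frame(x_um = 12, y_um = 0))
  expect_false(far$pericyte_associated)
  none <- associate_constrictions(ev, data.frame(x_um = numeric(0),
                                                 y_um = numeric(0)))
  expect_true(is.na(none$soma_distance))
  expect_false(none$pericyte_associated)
})

test_that("truth records are complete and in-bounds (generator contract)", {
  for (s in 1:5) {
    sc <- gen_vessel_scene(n_vessels = 3, constriction_spec = rep(0.3, 3),
                           n_somata = 2, pixel_size = 0.5, seed = s)
    tr <- sc$truth
    w_um <- tr$image_px[2] * tr$pixel_size
    h_um <- tr$image_px[1] * tr$pixel_size
    expect_equal(nrow(tr$constrictions), 3)
    expect_true(all(tr$constrictions$x_um > 0 & tr$constrictions$x_um < w_um))
    expect_true(all(tr$constrictions$y_um > 0 & tr$constrictions$y_um < h_um))
    expect_true(all(tr$somata$x_um > 0 & tr$somata$x_um < w_um))
    expect_false(any(duplicated(tr$constrictions[c("x_um", "y_um")])))
    # same seed reproduces the scene bit-identically
    sc2 <- gen_vessel_scene(n_vessels = 3, constriction_spec = rep(0.3, 3),
                            n_somata = 2, pixel_size = 0.5, seed = s)
    expect_identical(sc$image, sc2$image)
  }
})

test_that("marker coverage: full, absent, and half coverage", {
  img <- tube_image(diameter = 6)
  mask <- segment_vessels(img, 0.5)
  full <- marker_coverage(img, mask)
  expect_equal(full$coverage, 1)
  none <- marker_coverage(matrix(0, nrow(img), ncol(img)), mask)
  expect_equal(none$coverage, 0)
  # marker on exactly the left half of the tube
  half_marker <- img
  half_marker[, 121:240] <- 0
  half <- marker_coverage(half_marker, mask)
  expect_equal(half$coverage, 0.5, tolerance = 0.02)
  expect_equal(marker_coverage(half_marker, mask,
                               reference_value = 0.25)$fold_change,
               half$coverage / 0.25)
  blankmask <- segment_vessels(matrix(0, 20, 20), 0.5)
  expect_error(marker_coverage(matrix(0, 20, 20), blankmask), "undefined")
})
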