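# shared fixtures, all generated in code

tube_image <- function(nr = 120, nc = 240, diameter = 6, y_um = 30.1,
                       pixel_size = 0.5, x_range_um = c(10, 110)) {
  img <- matrix(0, nr, nc)
  strokeflow:::render_tube(img, cbind(x_range_um, rep(y_um, 2)),
                           rep(diameter, 2), pixel_size)
}

y_tube_image <- function(pixel_size = 0.5) {
  img <- matrix(0, 200, 200)
  img <- strokeflow:::render_tube(img, cbind(c(10, 50), c(50, 50)),
                                  c(6, 6), pixel_size)
  img <- strokeflow:::render_tube(img, cbind(c(50, 90), c(50, 20)),
                                  c(5, 5), pixel_size)
  strokeflow:::render_tube(img, cbind(c(50, 90), c(50, 80)),
                           c(5, 5), pixel_size)
}

# uniform-ICT speckle scene pushed through the full flowmetry chain
roundtrip_mean_ict <- function(ict, exposure = 5e-3, size = 128, seed = 11,
                               window = 7) {
  sc <- flow_scene(matrix(ict, size, size))
  st <- gen_speckle_stack(sc, exposure = exposure, beta = 1, n_frames = 2,
                          seed = seed, window = window)
  ict_s <- suppressWarnings(contrast_to_ict(spatial_contrast(st, window)))
  r <- (window + 1):(size - window)
  mean(ict_s$ict[r, r, ], na.rm = TRUE)
}
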