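# Rendering helpers ---------------------------------------------------------

# Render a tube with Gaussian cross-section along a polyline (um coords).
# The full width at half maximum of the cross-section equals the local
# diameter, so half-maximum thresholding recovers the nominal diameter.
# Overlaps combine by max, not sum, to keep amplitudes bounded.
render_tube <- function(img, path_um, diam_um, pixel_size, amplitude = 1,
                        step_px = 0.5) {
  nr <- nrow(img); nc <- ncol(img)
  # densify the polyline
  pts <- path_um
  if (nrow(pts) < 2) stopf("polyline needs >= 2 points")
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s_out <- seq(0, total, by = step_px * pixel_size)
  x <- stats::approx(cum, pts[, 1], xout = s_out)$y
  y <- stats::approx(cum, pts[, 2], xout = s_out)$y
  d <- stats::approx(cum, diam_um, xout = s_out)$y
  for (i in seq_along(s_out)) {
    rad_px <- ceiling(1.8 * d[i] / pixel_size / 2) + 1L
    ci <- round(y[i] / pixel_size + 0.5) # row index of nearest pixel
    cj <- round(x[i] / pixel_size + 0.5)
    ri <- max(1L, ci - rad_px):min(nr, ci + rad_px)
    rj <- max(1L, cj - rad_px):min(nc, cj + rad_px)
    if (!length(ri) || !length(rj)) next
    py <- (ri - 0.5) * pixel_size
    px <- (rj - 0.5) * pixel_size
    d2 <- outer((py - y[i])^2, (px - x[i])^2, "+")
    val <- amplitude * exp(-4 * log(2) * d2 / d[i]^2)
    img[ri, rj] <- pmax(img[ri, rj], val)
  }
  img
}

render_blob <- function(img, center_um, diameter_um, pixel_size,
                        amplitude = 1) {
  render_tube(img,
              rbind(center_um - c(1e-6, 0), center_um + c(1e-6, 0)),
              rep(diameter_um, 2), pixel_size, amplitude)
}

# Gaussian dip profile along the tube axis: diameter multiplier
constriction_profile <- function(s, positions, fractions, sigma_um = 3) {
  mult <- rep(1, length(s))
  for (i in seq_along(positions)) {
    mult <- mult * (1 - fractions[i] *
                      exp(-(s - positions[i])^2 / (2 * sigma_um^2)))
  }
  mult
}

#' Synthetic multichannel microscopy scene with planted constrictions
#'
#' Renders a three-channel image emulating the ex vivo readout: channel 1 a
#' vessel (lectin-analogue) channel with tubes of Gaussian cross-section
#' (FWHM = local diameter) carrying planted focal narrowings; channel 2 a
#' mural-cell soma (CD13-analogue) channel with Gaussian blobs; channel 3 a
#' uniform brightfield. Vessels are horizontal tubes at well-separated
#' rows; somata are placed adjacent to planted constrictions (within the
#' association radius) while constrictions remain, then at random positions
#' on vessels far from any constriction.
#'
#' @param n_vessels Number of vessels.
#' @param constriction_spec Numeric vector of narrowing fractions in (0,1),
#'   distributed round-robin over the vessels.
#' @param n_somata Number of somata to plant.
#' @param pixel_size Pixel size in um/pixel.
#' @param noise_sd Additive Gaussian noise sd (signal amplitude is 1, so
#'   `noise_sd = 0.1` is SNR 10).
#' @param seed Integer seed.
#' @param image_px Image size `c(rows, cols)` in pixels.
#' @param baseline_diameters Baseline vessel diameters in um (recycled);
#'   default draws from 5-7 um (capillary range).
#' @param soma_diameter_um Soma FWHM diameter in um.
#' @param soma_offset_um Perpendicular offset of constriction-adjacent
#'   somata from the vessel centerline, in um.
#' @return List with `image` (rows x cols x 3 array) and `truth`, a
#'   `vessel_scene_truth` with centerlines, baseline diameters, planted
#'   constrictions (x/y um, narrowing), somata centroids, branchpoints and
#'   the pixel size.
#' @export
gen_vessel_scene <- function(n_vessels = 2, constriction_spec = c(0.3, 0.3),
                             n_somata = 0, pixel_size = 0.5, noise_sd = 0,
                             seed = 1, image_px = c(192, 192),
                             baseline_diameters = NULL,
                             soma_diameter_um = 7, soma_offset_um = 4) {
  if (pixel_size <= 0) stopf("`pixel_size` must be > 0")
  if (length(constriction_spec) &&
      any(constriction_spec <= 0 | constriction_spec >= 1)) {
    stopf("narrowing fractions must be in (0, 1)")
  }
  nr <- image_px[1]; nc <- image_px[2]
  h_um <- nr * pixel_size; w_um <- nc * pixel_size
  margin <- 8 # um, keep tubes inside bounds
  if (n_vessels * 16 > h_um - 2 * margin) {
    stopf("image too small to hold %d vessels without overlap", n_vessels)
  }
  out <- with_seed(seed, {
    diam <- if (is.null(baseline_diameters)) {
      stats::runif(n_vessels, 5, 7)
    } else rep(baseline_diameters, length.out = n_vessels)
    rows_um <- seq(margin + 8, h_um - margin - 8, length.out = n_vessels)
    if (n_vessels > 1) rows_um <- rows_um + stats::runif(n_vessels, -3, 3)
    # assign constrictions round-robin
    vidx <- if (length(constriction_spec)) {
      rep(seq_len(n_vessels), length.out = length(constriction_spec))
    } else integer(0)
    ch1 <- matrix(0, nr, nc)
    centerlines <- vector("list", n_vessels)
    constr <- data.frame(vessel = integer(0), x_um = numeric(0),
                         y_um = numeric(0), narrowing = numeric(0),
                         baseline_diameter = numeric(0))
    for (v in seq_len(n_vessels)) {
      x0 <- margin; x1 <- w_um - margin
      s <- seq(0, x1 - x0, by = 0.5 * pixel_size)
      fr <- constriction_spec[vidx == v]
      # positions well inside the tube, >= 40 um apart
      pos <- numeric(0)
      if (length(fr)) {
        lo <- 25; hi <- (x1 - x0) - 25
        cand <- seq(lo, hi, length.out = length(fr) + 2)[-c(1, length(fr) + 2)]
        pos <- cand + stats::runif(length(fr), -5, 5)
      }
      dprof <- diam[v] * constriction_profile(s, pos, fr)
      path <- cbind(x0 + s, rep(rows_um[v], length(s)))
      ch1 <- render_tube(ch1, path, dprof, pixel_size)
      centerlines[[v]] <- path[c(1, nrow(path)), ]
      if (length(fr)) {
        constr <- rbind(constr, data.frame(
          vessel = v, x_um = x0 + pos, y_um = rows_um[v],
          narrowing = fr, baseline_diameter = diam[v]))
      }
    }
    # somata: adjacent to constrictions first, then on-vessel away from them
    ch2 <- matrix(0, nr, nc)
    somata <- data.frame(x_um = numeric(0), y_um = numeric(0))
    if (n_somata > 0) {
      k <- min(n_somata, nrow(constr))
      if (k > 0) {
        somata <- data.frame(
          x_um = constr$x_um[seq_len(k)],
          y_um = constr$y_um[seq_len(k)] + soma_offset_um)
      }
      extra <- n_somata - k
      tries <- 0
      while (extra > 0 && tries < 200) {
        tries <- tries + 1
        v <- sample.int(n_vessels, 1)
        xs <- stats::runif(1, margin + 10, w_um - margin - 10)
        ys <- rows_um[v] + soma_offset_um
        dmin <- if (nrow(constr)) {
          min(sqrt((constr$x_um - xs)^2 + (constr$y_um - ys)^2))
        } else Inf
        dsoma <- if (nrow(somata)) {
          min(sqrt((somata$x_um - xs)^2 + (somata$y_um - ys)^2))
        } else Inf
        if (dmin > 25 && dsoma > 2 * soma_diameter_um) {
          somata <- rbind(somata, data.frame(x_um = xs, y_um = ys))
          extra <- extra - 1
        }
      }
      if (extra > 0) stopf("could not place %d somata without overlap", extra)
      for (i in seq_len(nrow(somata))) {
        ch2 <- render_blob(ch2, c(somata$x_um[i], somata$y_um[i]),
                           soma_diameter_um, pixel_size)
      }
    }
    ch3 <- matrix(0.5, nr, nc)
    img <- array(0, c(nr, nc, 3))
    img[, , 1] <- ch1; img[, , 2] <- ch2; img[, , 3] <- ch3
    if (noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    }
    truth <- structure(list(
      centerlines = centerlines,
      baseline_diameters = diam,
      constrictions = constr,
      somata = somata,
      branchpoints = data.frame(x_um = numeric(0), y_um = numeric(0)),
      pixel_size = pixel_size,
      image_px = c(nr, nc)),
      class = "vessel_scene_truth")
    list(image = img, truth = truth)
  })
  out
}

#' @export
print.vessel_scene_truth <- function(x, ...) {
  cat(sprintf(
    "vessel_scene_truth: %d vessel(s), %d constriction(s), %d soma(ta), %.2f um/px\n",
    length(x$centerlines), nrow(x$constrictions), nrow(x$somata),
    x$pixel_size))
  invisible(x)
}
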