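disc_kernel <- function(radius_px) {
  r <- max(1L, round(radius_px))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Peri-microvascular measurement and background regions
#'
#' Builds the region the stain intensity is measured over (the vessel mask
#' dilated by `ring_width_um`; 0 means the vessel mask itself, matching
#' measurement "over the selected microvessels") and the background region
#' (the image complement outside a guard dilation of `guard_um` around all
#' vessels).
#'
#' @param mask A `vessel_mask`.
#' @param ring_width_um Dilation of the measurement region in um
#'   (default 0).
#' @param guard_um Guard margin excluded from the background, um
#'   (default 10).
#' @return List with logical matrices `region` and `background`.
#' @export
perivascular_region <- function(mask, ring_width_um = 0, guard_um = 10) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (ring_width_um < 0) stopf("`ring_width_um` must be >= 0")
  m <- mask$mask
  region <- if (ring_width_um == 0) m else {
    as.matrix(EBImage::imageData(EBImage::dilate(
      EBImage::Image(m * 1), disc_kernel(ring_width_um / mask$pixel_size)))) > 0
  }
  guard <- as.matrix(EBImage::imageData(EBImage::dilate(
    EBImage::Image(m * 1),
    disc_kernel(max(guard_um, ring_width_um) / mask$pixel_size)))) > 0
  background <- !guard
  if (all(region)) stopf("measurement region covers the whole image")
  if (!any(background)) stopf("no background left outside the guard margin")
  list(region = region, background = background)
}

#' Peri-microvascular stain intensity normalized to background
#'
#' Mean brightfield intensity over the peri-microvascular region
#' proportioned to the mean background intensity. Under
#' `polarity = "increase"` (stain raises the recorded signal) the fold is
#' `mean(region) / mean(background)`; under `"decrease"` (denser stain
#' darkens the brightfield) it is `mean(background) / mean(region)`, so a
#' fold > 1 always means more stain. The fold is invariant to global
#' illumination scaling.
#'
#' @param brightfield 2-D intensity image.
#' @param region,background Logical masks (disjoint, non-empty), e.g. from
#'   [perivascular_region()].
#' @param polarity `"increase"` or `"decrease"`.
#' @param scheme Optional semi-quantitative scale `c(max_level, step)`
#'   applied to the fold (see [semiquant_scale()]).
#' @return A `perivascular_intensity` list: `region_mean`,
#'   `background_mean`, `fold`, `polarity`, `scale_level` (NA without a
#'   scheme).
#' @export
intensity_fold <- function(brightfield, region, background,
                           polarity = c("increase", "decrease"),
                           scheme = NULL) {
  polarity <- match.arg(polarity)
  brightfield <- as.matrix(brightfield)
  stopifnot(is.logical(region), is.logical(background),
            all(dim(region) == dim(brightfield)),
            all(dim(background) == dim(brightfield)))
  if (!any(region) || !any(background)) {
    stopf("region and background must be non-empty")
  }
  if (any(region & background)) stopf("region and background must be disjoint")
  region_mean <- mean(brightfield[region])
  background_mean <- mean(brightfield[background])
  if (background_mean == 0) stopf("zero background mean")
  fold <- if (polarity == "increase") region_mean / background_mean
          else background_mean / region_mean
  level <- if (is.null(scheme)) NA_real_ else
    semiquant_scale(fold, max_level = scheme[1], step = scheme[2])
  structure(list(region_mean = region_mean,
                 background_mean = background_mean,
                 fold = fold, polarity = polarity, scale_level = level),
            class = "perivascular_intensity")
}

#' @export
print.perivascular_intensity <- function(x, ...) {
  cat(sprintf("perivascular_intensity: region %.3f / background %.3f -> fold %.3f (%s)\n",
              x$region_mean, x$background_mean, x$fold, x$polarity))
  if (!is.na(x$scale_level)) cat(sprintf("  scale level: %g\n", x$scale_level))
  invisible(x)
}

#' Bin an intensity fold onto a semi-quantitative scale
#'
#' Maps the fold to the nearest multiple of `step`, clamped to
#' `[0, max_level]`; ties round half-up. The study uses 0-6 in steps of 1
#' for glycogenolysis-inhibited animals and 0-1 in steps of 0.2 for
#' ischemic animals.
#'
#' @param fold Non-negative intensity fold.
#' @param max_level Scale maximum (a multiple of `step`).
#' @param step Scale increment (> 0).
#' @return The binned scale level.
#' @export
semiquant_scale <- function(fold, max_level = 6, step = 1) {
  if (any(fold < 0)) stopf("`fold` must be non-negative")
  if (step <= 0) stopf("`step` must be > 0")
  if (abs(max_level / step - round(max_level / step)) > 1e-9) {
    stopf("`max_level` must be a multiple of `step`")
  }
  lev <- floor(fold / step + 0.5 + 1e-12) * step
  pmin(pmax(lev, 0), max_level)
}

#' Synthetic histology scene with a known stain fold
#'
#' Renders a two-channel image: channel 1 a fluorescent vessel channel
#' (tubes of Gaussian cross-section) and channel 2 a brightfield whose
#' mean intensity over the vessel footprint, proportioned to the
#' background mean, equals `stain_fold` after the polarity convention
#' (exactly, at zero noise).
#'
#' @param stain_fold True peri-microvascular stain ratio over background
#'   (> 0).
#' @param polarity `"increase"` or `"decrease"`.
#' @param seed Integer seed.
#' @param noise_sd Additive Gaussian noise sd, as a fraction of the
#'   background level.
#' @param background_level Mean brightfield background intensity.
#' @param image_px Image size in pixels.
#' @param pixel_size um/pixel.
#' @param n_vessels Number of tubes.
#' @return List with `image` (rows x cols x 2), `truth`
#'   (`histology_scene_truth`: `stain_fold`, `background_level`,
#'   `polarity`, `vessel_mask`).
#' @export
gen_histology_scene <- function(stain_fold, polarity = c("increase", "decrease"),
                                seed = 1, noise_sd = 0,
                                background_level = 100,
                                image_px = c(160, 160), pixel_size = 0.5,
                                n_vessels = 2) {
  polarity <- match.arg(polarity)
  if (stain_fold <= 0) stopf("`stain_fold` must be > 0")
  if (background_level <= 0) stopf("`background_level` must be > 0")
  nr <- image_px[1]; nc <- image_px[2]
  with_seed(seed, {
    ch1 <- matrix(0, nr, nc)
    rows_um <- seq(0.25, 0.75, length.out = n_vessels) * nr * pixel_size
    for (v in seq_len(n_vessels)) {
      path <- cbind(c(6, nc * pixel_size - 6), rep(rows_um[v], 2))
      ch1 <- render_tube(ch1, path, rep(6, 2), pixel_size)
    }
    vmask <- ch1 >= 0.5
    region_value <- if (polarity == "increase") {
      background_level * stain_fold
    } else {
      background_level / stain_fold
    }
    ch2 <- matrix(background_level, nr, nc)
    ch2[vmask] <- region_value
    if (noise_sd > 0) {
      ch2 <- ch2 + stats::rnorm(length(ch2), 0, noise_sd * background_level)
    }
    img <- array(0, c(nr, nc, 2))
    img[, , 1] <- ch1; img[, , 2] <- ch2
    truth <- structure(list(stain_fold = stain_fold,
                            background_level = background_level,
                            polarity = polarity,
                            vessel_mask = vmask,
                            pixel_size = pixel_size),
                       class = "histology_scene_truth")
    list(image = img, truth = truth)
  })
}
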