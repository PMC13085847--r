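#' Per-pixel spatial speckle contrast
#'
#' Computes `K = sd / mean` of intensity over a square moving window for
#' every pixel of every frame. The standard deviation uses the population
#' form (denominator `N`, the number of pixels in the window); borders use
#' the truncated window. Pixels with zero local mean are marked invalid
#' (`NA`).
#'
#' @param stack A `speckle_stack` (see [gen_speckle_stack()]), or a plain
#'   numeric array/matrix of non-negative intensities.
#' @param window Odd window size in pixels (>= 3); 7 is common practice.
#' @return A `contrast_series`: list with `contrast` (array, same shape as
#'   the input frames), `window`, and `exposure` if known.
#' @export
spatial_contrast <- function(stack, window = 7) {
  exposure <- NULL
  if (inherits(stack, "speckle_stack")) {
    frames <- stack$frames
    exposure <- stack$exposure
  } else {
    frames <- stack
  }
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  check_odd_window(window, dim(frames)[1:2])
  if (any(frames < 0, na.rm = TRUE)) stopf("intensities must be non-negative")
  out <- array(NA_real_, dim(frames))
  for (t in seq_len(dim(frames)[3])) {
    st <- local_mean_sd(frames[, , t], window)
    k <- st$sd / st$mean
    k[st$mean == 0] <- NA_real_
    out[, , t] <- k
  }
  structure(list(contrast = out, window = as.integer(window),
                 exposure = exposure),
            class = "contrast_series")
}

#' Convert a contrast series to inverse correlation times
#'
#' Applies the nonlinear inversion of the single-exposure speckle model
#' (see [ict_from_contrast()]) to every pixel of every contrast frame.
#' Contrast at or above `sqrt(beta)` clamps to ICT 0; the total clamp count
#' is kept in the `n_clamped` field. Invalid pixels propagate as `NA`.
#'
#' @param contrast A `contrast_series` from [spatial_contrast()].
#' @param exposure Camera exposure time in seconds; defaults to the value
#'   carried by the series, if any.
#' @param beta Coherence factor in (0, 1].
#' @return An `ict_series`: list with `ict` (array, 1/s), `beta`,
#'   `exposure`, `n_clamped`.
#' @export
contrast_to_ict <- function(contrast, exposure = NULL, beta = 1) {
  stopifnot(inherits(contrast, "contrast_series"))
  exposure <- exposure %||% contrast$exposure
  if (is.null(exposure)) stopf("`exposure` required (not carried by input)")
  ict <- ict_from_contrast(contrast$contrast, exposure, beta)
  n_clamped <- attr(ict, "n_clamped")
  attr(ict, "n_clamped") <- NULL
  if (n_clamped > 0) {
    warning(sprintf("%d pixel(s) with contrast above the model ceiling clamped to ICT 0",
                    n_clamped), call. = FALSE)
  }
  structure(list(ict = ict, beta = beta, exposure = exposure,
                 n_clamped = n_clamped),
            class = "ict_series")
}

n_frames_of <- function(series) dim(series$ict)[3]

#' Baseline ICT image by temporal averaging
#'
#' Per-pixel arithmetic mean of `n_frames` consecutive ICT frames starting
#' at `start_frame` — the pre-ischemic baseline image (the study averages
#' the 10 frames immediately preceding ischemia onset).
#'
#' @param series An `ict_series`.
#' @param start_frame First frame of the baseline block (1-based).
#' @param n_frames Number of frames to average (default 10).
#' @return A baseline ICT matrix (1/s).
#' @export
baseline_map <- function(series, start_frame = 1, n_frames = 10) {
  stopifnot(inherits(series, "ict_series"))
  if (start_frame < 1 || start_frame + n_frames - 1 > n_frames_of(series)) {
    stopf("baseline frames [%d, %d] outside the series (1..%d)",
          start_frame, start_frame + n_frames - 1, n_frames_of(series))
  }
  idx <- seq(start_frame, length.out = n_frames)
  m <- series$ict[, , idx, drop = FALSE]
  apply(m, c(1, 2), mean)
}

#' Relative CBF series: ICT frames divided by the baseline image
#'
#' Each ICT frame is divided pixel-wise by the baseline image to yield
#' relative cerebral blood flow (ratio 1 = baseline flow). Pixels whose
#' baseline is 0 (or NA) are marked invalid.
#'
#' @param series An `ict_series`.
#' @param baseline Baseline ICT matrix from [baseline_map()].
#' @return An `rcbf_series`: list with `ratio` (array) and `baseline`.
#' @export
relative_cbf_series <- function(series, baseline) {
  stopifnot(inherits(series, "ict_series"))
  baseline <- as.matrix(baseline)
  if (!all(dim(baseline) == dim(series$ict)[1:2])) {
    stopf("baseline shape does not match the series")
  }
  if (any(baseline < 0, na.rm = TRUE)) stopf("baseline must be >= 0")
  nz <- baseline
  nz[nz == 0] <- NA_real_
  ratio <- sweep(series$ict, c(1, 2), nz, "/")
  structure(list(ratio = ratio, baseline = baseline),
            class = "rcbf_series")
}

#' Epoch-averaged percent flow change map
#'
#' Averages the relative-CBF ratio over an epoch of frames and expresses it
#' as percent change from baseline: `100 * (mean ratio - 1)`. This is the
#' per-pixel average percent flow change during ischemia when the epoch is
#' the occlusion period.
#'
#' @param ratios An `rcbf_series` from [relative_cbf_series()].
#' @param epoch Integer vector of frame indices, or `c(start, end)` if
#'   length 2 with `end >= start`.
#' @return A `delta_cbf_map`: list with `percent_change` (matrix) and
#'   `epoch`.
#' @export
epoch_mean_change <- function(ratios, epoch) {
  stopifnot(inherits(ratios, "rcbf_series"))
  if (length(epoch) == 2 && epoch[2] >= epoch[1]) {
    epoch <- seq(epoch[1], epoch[2])
  }
  epoch <- as.integer(epoch)
  if (length(epoch) == 0) stopf("empty epoch")
  if (any(epoch < 1 | epoch > dim(ratios$ratio)[3])) {
    stopf("epoch outside the series")
  }
  m <- ratios$ratio[, , epoch, drop = FALSE]
  pc <- 100 * (apply(m, c(1, 2), mean) - 1)
  structure(list(percent_change = pc, epoch = range(epoch)),
            class = "delta_cbf_map")
}

#' Pseudocolor rendering of a percent flow-change map
#'
#' Symmetric diverging colormap: cold colors for flow decreases (0 down to
#' -clip percent), hot colors for increases (0 up to +clip percent), white
#' at 0. Values beyond the clip render at the extremes; invalid pixels
#' render dark gray.
#'
#' @param map A `delta_cbf_map`, or a plain numeric matrix of percent
#'   changes.
#' @param clip Positive clip limit in percent (default 100).
#' @return rows x cols x 3 RGB array in `[0, 1]` (class `pseudocolor_map`),
#'   writable with [png::writePNG].
#' @export
pseudocolor_map <- function(map, clip = 100) {
  if (inherits(map, "delta_cbf_map")) map <- map$percent_change
  if (clip <= 0) stopf("`clip` must be > 0")
  v <- pmax(pmin(map / clip, 1), -1)
  ramp <- grDevices::colorRamp(c("#053061", "#2166AC", "#F7F7F7",
                                 "#B2182B", "#67001F"), space = "Lab")
  rgb <- array(0.25, c(nrow(map), ncol(map), 3)) # invalid: dark gray
  ok <- !is.na(v)
  if (any(ok)) {
    cols <- ramp((as.numeric(v[ok]) + 1) / 2) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ok] <- cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  structure(rgb, class = c("pseudocolor_map", "array"))
}

#' ROI means and standard errors of a flow-change map
#'
#' Mean and standard error (sd with denominator n-1, over sqrt(n)) of the
#' percent-change values over the valid pixels of each region of interest,
#' e.g. the ischemic core and the peri-infarct (penumbra) ROI.
#'
#' @param map A `delta_cbf_map` or percent-change matrix.
#' @param rois Named list of logical masks (same shape as the map).
#' @return data.frame with one row per ROI: `roi`, `mean`, `se`, `n_valid`,
#'   `n_invalid`, `all_invalid`.
#' @export
roi_mean_change <- function(map, rois) {
  if (inherits(map, "delta_cbf_map")) map <- map$percent_change
  if (!is.list(rois) || length(rois) == 0) stopf("`rois` must be a non-empty list")
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  res <- lapply(names(rois), function(nm) {
    mask <- rois[[nm]]
    if (!is.logical(mask) || !all(dim(mask) == dim(map))) {
      stopf("ROI '%s' is not a logical mask matching the map", nm)
    }
    if (!any(mask)) stopf("ROI '%s' is empty", nm)
    vals <- map[mask]
    valid <- vals[!is.na(vals)]
    n <- length(valid)
    data.frame(roi = nm,
               mean = if (n) mean(valid) else NA_real_,
               se = if (n > 1) stats::sd(valid) / sqrt(n) else if (n == 1) 0 else NA_real_,
               n_valid = n,
               n_invalid = sum(is.na(vals)),
               all_invalid = n == 0)
  })
  out <- do.call(rbind, res)
  if (any(out$all_invalid)) {
    warning("ROI(s) with no valid pixels: ",
            paste(out$roi[out$all_invalid], collapse = ", "), call. = FALSE)
  }
  out
}
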