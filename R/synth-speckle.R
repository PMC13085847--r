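#' Ground-truth flow scene for speckle synthesis
#'
#' A flow scene holds the per-pixel ground-truth inverse correlation time
#' (ICT, 1/s, proportional to flow speed) and a list of temporal epochs
#' during which the whole ICT field is scaled by a multiplicative flow
#' factor (e.g. factor 0.3 models a 70 percent flow drop in the pixels it
#' applies to).
#'
#' @param ict_map Matrix of non-negative, finite inverse correlation times
#'   (1/s).
#' @param epochs `NULL`, or a data.frame with columns `start`, `end`
#'   (frame indices, inclusive) and `factor` (> 0). Epochs must be ordered
#'   and non-overlapping. An optional logical-matrix column-attribute is not
#'   supported; use `region` to restrict an epoch spatially.
#' @param region Optional logical matrix (same shape as `ict_map`): pixels
#'   the epoch factors apply to. Default: all pixels.
#' @return An object of class `flow_scene`.
#' @export
flow_scene <- function(ict_map, epochs = NULL, region = NULL) {
  ict_map <- as.matrix(ict_map)
  if (any(!is.finite(ict_map)) || any(ict_map < 0)) {
    stopf("`ict_map` must be finite and non-negative")
  }
  if (!is.null(epochs)) {
    epochs <- as.data.frame(epochs)
    if (!all(c("start", "end", "factor") %in% names(epochs))) {
      stopf("`epochs` needs columns start, end, factor")
    }
    if (any(epochs$factor <= 0)) stopf("epoch flow factors must be > 0")
    if (any(epochs$end < epochs$start)) stopf("epoch end before start")
    if (nrow(epochs) > 1) {
      o <- order(epochs$start)
      if (!identical(o, seq_len(nrow(epochs)))) stopf("epochs must be ordered")
      if (any(epochs$start[-1] <= epochs$end[-nrow(epochs)])) {
        stopf("epochs must be non-overlapping")
      }
    }
  }
  if (!is.null(region)) {
    stopifnot(is.logical(region), all(dim(region) == dim(ict_map)))
  }
  structure(list(ict_map = ict_map, epochs = epochs, region = region,
                 shape = dim(ict_map)),
            class = "flow_scene")
}

epoch_factor_for_frame <- function(scene, frame) {
  if (is.null(scene$epochs)) return(1)
  hit <- scene$epochs$start <= frame & scene$epochs$end >= frame
  if (any(hit)) scene$epochs$factor[which(hit)[1]] else 1
}

#' Synthesize a raw speckle frame stack from a flow scene
#'
#' Draws per-pixel intensities whose local spatial statistics reproduce the
#' forward-model contrast `K(T * ICT; beta)` at each pixel's epoch-scaled
#' ground-truth ICT (a variance-matched noise field): each frame is
#' `mu * (1 + K * Z)` where `Z` is a zero-mean, unit-sd noise texture
#' whose statistics over the declared window are exact by construction
#' (see the methods vignette), so the measured window contrast matches the
#' target at every interior pixel. This is a statistical emulation of
#' speckle, not a coherent field simulation; the downstream pipeline
#' consumes only the contrast statistics.
#'
#' @param scene A [flow_scene()].
#' @param exposure Camera exposure time in seconds (the study value is 5 ms).
#' @param beta Coherence factor in (0, 1]; defaults to 1.
#' @param n_frames Number of frames.
#' @param seed Integer seed; the stack is a pure function of the arguments.
#' @param window Odd window size (pixels) the contrast statistics are
#'   matched over; use the same window in [spatial_contrast()].
#' @param frame_interval Seconds between frames (study value 10 s).
#' @param mean_intensity Mean detector intensity (arbitrary units).
#' @return A `speckle_stack`: list with `frames` (rows x cols x n_frames
#'   array), `exposure`, `frame_interval`, `timestamps`, and the ground
#'   truth `scene`.
#' @export
gen_speckle_stack <- function(scene, exposure, beta = 1, n_frames, seed,
                              window = 7, frame_interval = 10,
                              mean_intensity = 100) {
  stopifnot(inherits(scene, "flow_scene"))
  if (length(exposure) != 1L || !is.finite(exposure) || exposure <= 0) {
    stopf("`exposure` must be a single positive number (seconds)")
  }
  check_beta(beta)
  if (n_frames < 1) stopf("`n_frames` must be >= 1")
  check_odd_window(window, dim(scene$ict_map))
  if (!is.null(scene$epochs) && any(scene$epochs$end > n_frames)) {
    stopf("scene epochs exceed n_frames = %d", n_frames)
  }
  d <- dim(scene$ict_map)
  region <- scene$region %||% matrix(TRUE, d[1], d[2])
  frames <- array(NA_real_, c(d[1], d[2], n_frames))
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      fac <- epoch_factor_for_frame(scene, t)
      ict <- scene$ict_map
      ict[region] <- ict[region] * fac
      k <- speckle_contrast(exposure * ict, beta)
      z <- speckle_noise_field(d[1], d[2], window)
      frames[, , t] <- pmax(mean_intensity * (1 + k * z), 0)
    }
  })
  structure(list(frames = frames,
                 exposure = exposure,
                 frame_interval = frame_interval,
                 timestamps = (seq_len(n_frames) - 1) * frame_interval,
                 window = as.integer(window),
                 beta = beta,
                 scene = scene),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_stack: %d x %d pixels, %d frames, exposure %g ms, interval %g s\n",
              d[1], d[2], d[3], x$exposure * 1e3, x$frame_interval))
  invisible(x)
}
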