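#' Constriction-detection benchmark on seeded synthetic scenes
#'
#' Generates `n_scenes` vessel scenes with planted focal narrowings, runs
#' the full detection pipeline (segmentation with supersampling, skeleton
#' graph, rule-based detection), and scores detections against the truth
#' sidecar: a detection within `match_radius_um` of a planted narrowing
#' deeper than the detection threshold is a true positive; every other
#' detection is a false positive; planted super-threshold narrowings with
#' no detection are false negatives.
#'
#' @param n_scenes Number of scenes.
#' @param narrowing Planted narrowing fraction.
#' @param noise_sd Scene noise sd (amplitude 1; 0.1 = SNR 10).
#' @param seed Base seed; scene `i` uses `seed + i`.
#' @param narrowing_threshold Detection threshold (default 0.20).
#' @param n_vessels,pixel_size Passed to [gen_vessel_scene()].
#' @param baseline_diameters Passed to [gen_vessel_scene()].
#' @param smooth_sigma,supersample Passed to [segment_vessels()].
#' @param match_radius_um Match radius between detection and truth.
#' @return List with `recall`, `precision`, `fp_per_scene`, `tp`, `fp`,
#'   `fn`, `n_planted`, `n_scenes`.
#' @export
constriction_benchmark <- function(n_scenes = 50, narrowing = 0.30,
                                   noise_sd = 0.1, seed = 1,
                                   narrowing_threshold = 0.20,
                                   n_vessels = 2, pixel_size = 0.5,
                                   baseline_diameters = NULL,
                                   smooth_sigma = 3, supersample = 2,
                                   match_radius_um = 10) {
  tp <- fp <- fn <- planted <- 0L
  for (i in seq_len(n_scenes)) {
    sc <- gen_vessel_scene(n_vessels = n_vessels,
                           constriction_spec = rep(narrowing, n_vessels),
                           pixel_size = pixel_size, noise_sd = noise_sd,
                           seed = seed + i,
                           baseline_diameters = baseline_diameters)
    m <- segment_vessels(sc$image[, , 1], pixel_size,
                         smooth_sigma = if (noise_sd > 0) smooth_sigma else 0,
                         supersample = supersample)
    ev <- detect_constrictions(build_vessel_graph(m),
                               narrowing_threshold = narrowing_threshold)
    tr <- sc$truth$constrictions
    super <- tr$narrowing > narrowing_threshold
    planted <- planted + sum(super)
    matched <- rep(FALSE, nrow(tr))
    for (k in seq_len(nrow(ev))) {
      d <- sqrt((tr$x_um - ev$x_um[k])^2 + (tr$y_um - ev$y_um[k])^2)
      j <- which.min(d)
      if (length(j) && d[j] < match_radius_um && !matched[j] && super[j]) {
        matched[j] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(super & !matched)
  }
  list(recall = if (planted) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp) tp / (tp + fp) else 1,
       fp_per_scene = fp / n_scenes,
       tp = tp, fp = fp, fn = fn, n_planted = planted, n_scenes = n_scenes)
}
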