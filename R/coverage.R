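#' Marker coverage of the microvascular network
#'
#' Fraction of the vessel skeleton that is positive for a marker (e.g. the
#' endothelial lactate transporter MCT-1): a skeleton point counts as
#' marker-positive when thresholded marker signal occupies at least half of
#' the vessel-mask pixels within one local-diameter distance of the
#' centerline point (restricting the neighborhood to the mask keeps tube
#' ends and partial-coverage boundaries unbiased). Reported as
#' a coverage fraction in [0, 1] and, when a reference coverage is given,
#' as fold change over that reference (the study reports coverage as fold
#' change over vehicle-treated animals).
#'
#' @param marker_channel 2-D intensity image of the marker.
#' @param mask A `vessel_mask` defining the vessel network.
#' @param reference_value Optional reference coverage for the fold change.
#' @param threshold Marker-positivity threshold; default is background +
#'   half the background-corrected peak (half-maximum).
#' @return List with `coverage`, `fold_change` (NA if no reference),
#'   `n_skeleton_px`, `threshold`.
#' @export
marker_coverage <- function(marker_channel, mask, reference_value = NULL,
                            threshold = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  marker_channel <- as.matrix(marker_channel)
  if (!all(dim(marker_channel) == dim(mask$mask))) {
    stopf("marker channel and mask shapes differ")
  }
  if (!any(mask$mask)) stopf("empty vessel mask: coverage undefined")
  skel <- skeletonize(mask$mask)
  if (!any(skel)) stopf("mask skeleton is empty: coverage undefined")
  dmap <- local_diameter_map(mask$mask, mask$pixel_size)
  if (is.null(threshold)) {
    bg <- stats::median(marker_channel)
    threshold <- bg +
      0.5 * (stats::quantile(marker_channel, 0.999, names = FALSE) - bg)
  }
  pos_img <- marker_channel > threshold # strict: a flat channel is negative
  sk <- which(skel, arr.ind = TRUE)
  nr <- nrow(skel); nc <- ncol(skel)
  positive <- logical(nrow(sk))
  for (i in seq_len(nrow(sk))) {
    r <- sk[i, 1]; c <- sk[i, 2]
    rad_px <- max(1L, ceiling(dmap[r, c] / mask$pixel_size))
    ri <- max(1L, r - rad_px):min(nr, r + rad_px)
    rj <- max(1L, c - rad_px):min(nc, c + rad_px)
    inmask <- mask$mask[ri, rj]
    positive[i] <- mean(pos_img[ri, rj][inmask]) >= 0.5
  }
  coverage <- mean(positive)
  list(coverage = coverage,
       fold_change = if (is.null(reference_value)) NA_real_ else
         coverage / reference_value,
       n_skeleton_px = nrow(sk),
       threshold = threshold)
}
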