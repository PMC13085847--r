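#' Detect focal capillary constrictions on a vessel graph
#'
#' Implements the study's counting rule: a constriction is a focal
#' narrowing of more than `narrowing_threshold` (default 20 percent)
#' relative to the upstream and/or downstream vessel segment, counted on
#' capillaries whose (reference) diameter is below
#' `capillary_max_diameter` (default 9 um). For every local minimum of the
#' (median-smoothed) diameter profile along an edge, the reference
#' diameter is the larger of the median diameters over the two flanking
#' windows `flank_um[1]`-`flank_um[2]` away from the minimum ("and/or" as
#' OR: the event fires if the narrowing exceeds the threshold versus
#' either flank). Minima closer than `min_separation_um` merge, keeping
#' the deepest. Edges too short to carry both flanking windows are
#' skipped; the count of skipped edges is reported as an attribute.
#'
#' @param graph A `vessel_graph`.
#' @param narrowing_threshold Fraction in (0,1); event requires
#'   `1 - local/reference > narrowing_threshold`.
#' @param capillary_max_diameter Only vessels with reference diameter below
#'   this (um) are counted.
#' @param min_separation_um Minima closer than this merge (um).
#' @param flank_um Flanking reference window, distances from the minimum
#'   (um), default `c(5, 15)`.
#' @param smooth_um Running-median window (um) applied to the diameter
#'   profile before minima detection.
#' @return A `constriction_events` data.frame: `x_um`, `y_um`,
#'   `local_diameter`, `reference_diameter`, `narrowing`, `edge`;
#'   attribute `n_skipped_edges`.
#' @export
detect_constrictions <- function(graph, narrowing_threshold = 0.20,
                                 capillary_max_diameter = 9,
                                 min_separation_um = 10,
                                 flank_um = c(5, 15), smooth_um = 3) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (narrowing_threshold <= 0 || narrowing_threshold >= 1) {
    stopf("`narrowing_threshold` must be in (0, 1)")
  }
  events <- list()
  skipped <- 0L
  for (ei in seq_along(graph$edges)) {
    e <- graph$edges[[ei]]
    n <- nrow(e$points)
    if (n < 3) next
    s <- c(0, cumsum(sqrt(rowSums((e$points[-1, , drop = FALSE] -
                                   e$points[-n, , drop = FALSE])^2))))
    if (s[n] < 2 * flank_um[2]) { skipped <- skipped + 1L; next }
    d <- e$diameter_um
    step <- s[n] / (n - 1)
    kw <- max(3L, 2L * floor(smooth_um / step / 2) + 1L)
    ds <- if (n > kw) stats::runmed(d, kw) else d
    # interior local minima (plateau-tolerant)
    cand <- which(diff(sign(diff(ds))) > 0) + 1L
    # plateaus: centers of runs where ds equals a local min of the run
    if (!length(cand)) next
    recs <- list()
    for (i in cand) {
      up <- which(s >= s[i] - flank_um[2] & s <= s[i] - flank_um[1])
      dn <- which(s >= s[i] + flank_um[1] & s <= s[i] + flank_um[2])
      if (!length(up) || !length(dn)) next
      ref <- max(stats::median(ds[up]), stats::median(ds[dn]))
      if (!is.finite(ref) || ref <= 0) next
      narrowing <- 1 - ds[i] / ref
      if (narrowing > narrowing_threshold && ref < capillary_max_diameter) {
        recs[[length(recs) + 1L]] <- data.frame(
          x_um = e$points[i, 1], y_um = e$points[i, 2],
          local_diameter = ds[i], reference_diameter = ref,
          narrowing = narrowing, edge = ei, s_um = s[i])
      }
    }
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    recs <- recs[order(recs$s_um), , drop = FALSE]
    # merge nearby minima, keep the deepest
    keep <- rep(TRUE, nrow(recs))
    i <- 1L
    while (i < nrow(recs)) {
      j <- i + 1L
      while (j <= nrow(recs) && keep[j] &&
             recs$s_um[j] - recs$s_um[i] < min_separation_um) {
        if (recs$narrowing[j] > recs$narrowing[i]) {
          keep[i] <- FALSE; i <- j
        } else keep[j] <- FALSE
        j <- j + 1L
      }
      i <- j
    }
    events[[length(events) + 1L]] <- recs[keep, , drop = FALSE]
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(x_um = numeric(0), y_um = numeric(0),
               local_diameter = numeric(0), reference_diameter = numeric(0),
               narrowing = numeric(0), edge = integer(0), s_um = numeric(0))
  out$s_um <- NULL
  rownames(out) <- NULL
  structure(out, n_skipped_edges = skipped,
            class = c("constriction_events", "data.frame"))
}

#' Annotate constrictions with nearest-soma distance and association
#'
#' Each event gains `soma_distance` (Euclidean distance to the nearest
#' soma centroid, um) and `pericyte_associated = soma_distance <
#' max_distance` (the study's "< 10 um from the pericyte soma" rule).
#' Events are retained regardless of association; use `associated_only` in
#' [disector_density()] to select the counted subset.
#'
#' @param events A `constriction_events` data.frame.
#' @param somata data.frame with `x_um`, `y_um` centroids (same frame).
#' @param max_distance Association radius in um (default 10).
#' @return The events with `soma_distance` and `pericyte_associated`
#'   columns added (`soma_distance` is `NA` when no somata exist).
#' @export
associate_constrictions <- function(events, somata, max_distance = 10) {
  n <- nrow(events)
  if (is.null(somata) || nrow(somata) == 0) {
    events$soma_distance <- rep(NA_real_, n)
    events$pericyte_associated <- rep(FALSE, n)
    return(events)
  }
  d <- vapply(seq_len(n), function(i) {
    min(sqrt((somata$x_um - events$x_um[i])^2 +
             (somata$y_um - events$y_um[i])^2))
  }, 0)
  events$soma_distance <- d
  events$pericyte_associated <- d < max_distance
  events
}

#' @export
print.constriction_events <- function(x, ...) {
  cat(sprintf("constriction_events: %d event(s)", nrow(x)))
  if ("pericyte_associated" %in% names(x)) {
    cat(sprintf(", %d pericyte-associated", sum(x$pericyte_associated)))
  }
  sk <- attr(x, "n_skipped_edges")
  if (!is.null(sk) && sk > 0) cat(sprintf(" (%d short edge(s) skipped)", sk))
  cat("\n")
  if (nrow(x)) print.data.frame(x, digits = 3)
  invisible(x)
}
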