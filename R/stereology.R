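#' Disector counting frames
#'
#' Constructs the stereological counting frames used to express event
#' counts as areal densities. The study's frame is 240 x 160 um (0.0384
#' mm^2 per field of view) with 40 um sampled thickness; 10 frames per
#' hemisphere per section and 10 sections give 100 frames, a total
#' evaluated area of 3.84 mm^2 per hemisphere.
#'
#' @param origin_x_um,origin_y_um Frame origins (top-left corner), um.
#' @param width_um,height_um Frame size in um (defaults 240 x 160).
#' @param z_um Sampled thickness along z in um (default 40; informational).
#' @return A `disector_frames` data.frame.
#' @export
disector_frames <- function(origin_x_um, origin_y_um, width_um = 240,
                            height_um = 160, z_um = 40) {
  stopifnot(length(origin_x_um) == length(origin_y_um))
  df <- data.frame(origin_x_um = origin_x_um, origin_y_um = origin_y_um,
                   width_um = width_um, height_um = height_um, z_um = z_um)
  if (frames_overlap(df)) stopf("disector frames must not overlap")
  class(df) <- c("disector_frames", "data.frame")
  df
}

frames_overlap <- function(df) {
  n <- nrow(df)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (df$origin_x_um[i] < df$origin_x_um[j] + df$width_um[j] &&
        df$origin_x_um[j] < df$origin_x_um[i] + df$width_um[i] &&
        df$origin_y_um[i] < df$origin_y_um[j] + df$height_um[j] &&
        df$origin_y_um[j] < df$origin_y_um[i] + df$height_um[i]) {
      return(TRUE)
    }
  }
  FALSE
}

#' Frame area in mm^2
#'
#' @param width_um,height_um Frame size in um.
#' @return Area in mm^2 (240 x 160 um gives 0.0384 mm^2).
#' @export
disector_frame_area_mm2 <- function(width_um = 240, height_um = 160) {
  (width_um / 1000) * (height_um / 1000)
}

#' Number of serial sections spanning an anteroposterior extent
#'
#' @param extent_mm Total anteroposterior extent in mm (study: 5 mm).
#' @param thickness_um Cutting thickness in um (study: 50 um).
#' @return Integer count (study: 100 sections, every 10th analyzed).
#' @export
sections_spanned <- function(extent_mm = 5, thickness_um = 50) {
  as.integer(round(extent_mm * 1000 / thickness_um))
}

points_in_frames <- function(x, y, frames) {
  # unbiased counting-frame edge rule: left/top edges inclusive,
  # right/bottom exclusive, so tiling frames count each point once
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(frames))) {
    hit <- hit |
      (x >= frames$origin_x_um[i] &
         x < frames$origin_x_um[i] + frames$width_um[i] &
         y >= frames$origin_y_um[i] &
         y < frames$origin_y_um[i] + frames$height_um[i])
  }
  hit
}

new_density_result <- function(count, total_area_mm2) {
  structure(list(count = count, total_area_mm2 = total_area_mm2,
                 density_per_mm2 = count / total_area_mm2),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("density_result: %d event(s) / %.4f mm^2 = %.2f per mm^2\n",
              x$count, x$total_area_mm2, x$density_per_mm2))
  invisible(x)
}

#' Constriction density over disector frames
#'
#' Counts constriction events falling inside any counting frame (each
#' event counted once; left/top edges count, right/bottom do not) and
#' expresses the count per mm^2 of total evaluated frame area.
#'
#' @param events A `constriction_events` data.frame (annotated by
#'   [associate_constrictions()] if `associated_only = TRUE`).
#' @param frames A `disector_frames` data.frame (non-overlapping).
#' @param associated_only Count only pericyte-associated events (default
#'   `TRUE`, matching the study's CD13-positive pericyte-associated
#'   counts). Requires the `pericyte_associated` column.
#' @return A `density_result`: `count`, `total_area_mm2`,
#'   `density_per_mm2`.
#' @export
disector_density <- function(events, frames, associated_only = TRUE) {
  if (frames_overlap(frames)) stopf("disector frames must not overlap")
  ev <- events
  if (associated_only) {
    if (!"pericyte_associated" %in% names(ev)) {
      stopf("`associated_only = TRUE` needs events annotated by associate_constrictions()")
    }
    ev <- ev[ev$pericyte_associated, , drop = FALSE]
  }
  total_area <- sum(frames$width_um * frames$height_um) / 1e6
  count <- if (nrow(ev)) sum(points_in_frames(ev$x_um, ev$y_um, frames)) else 0L
  new_density_result(as.integer(count), total_area)
}

#' Branch-point density over disector frames
#'
#' Counts junction nodes of a vessel graph inside the counting frames and
#' expresses them per mm^2.
#'
#' @param graph A `vessel_graph`.
#' @param frames A `disector_frames` data.frame.
#' @return A `density_result`.
#' @export
branchpoint_density <- function(graph, frames) {
  if (frames_overlap(frames)) stopf("disector frames must not overlap")
  jx <- graph$nodes[graph$nodes$type == "junction", , drop = FALSE]
  total_area <- sum(frames$width_um * frames$height_um) / 1e6
  count <- if (nrow(jx)) sum(points_in_frames(jx$x_um, jx$y_um, frames)) else 0L
  new_density_result(as.integer(count), total_area)
}
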