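#' @export
plot.delta_cbf_map <- function(x, clip = 100, main = "percent flow change",
                               ...) {
  rgb <- pseudocolor_map(x, clip = clip)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ncol(x$percent_change)),
                        ylim = c(0, nrow(x$percent_change)), asp = 1)
  graphics::rasterImage(grDevices::as.raster(unclass(rgb)), 0, 0,
                        ncol(x$percent_change), nrow(x$percent_change))
  graphics::title(main = main)
  invisible(x)
}

#' @export
plot.cuff_trace <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$time_s, x$pressure_mmHg, type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "cuff pressure (mmHg)", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$time_s, x$flow_au, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("tail flow (a.u.)", side = 4, line = 2.5)
  invisible(x)
}

#' @export
plot.vessel_graph <- function(x, events = NULL, somata = NULL, ...) {
  sk <- which(x$skeleton, arr.ind = TRUE)
  graphics::plot((sk[, 2] - 0.5) * x$pixel_size,
                 (sk[, 1] - 0.5) * x$pixel_size,
                 pch = ".", asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  jx <- x$nodes[x$nodes$type == "junction", ]
  if (nrow(jx)) graphics::points(jx$x_um, jx$y_um, pch = 1, col = "blue")
  if (!is.null(events) && nrow(events)) {
    graphics::points(events$x_um, events$y_um, pch = 4, col = "red", cex = 1.2)
  }
  if (!is.null(somata) && nrow(somata)) {
    graphics::points(somata$x_um, somata$y_um, pch = 17, col = "darkorange")
  }
  invisible(x)
}

#' Superplot of grouped measurements
#'
#' Draws per-section values as jittered points, per-animal medians as
#' larger symbols, and the group median with its interquartile range.
#'
#' @param data data.frame with `value`, `group`, `animal_id`.
#' @param ... Passed to [graphics::plot()].
#' @export
superplot <- function(data, ...) {
  sm <- superplot_summary(data)
  g <- factor(data$group)
  xi <- as.integer(g)
  graphics::plot(jitter(xi, amount = 0.12), data$value, xaxt = "n",
                 xlab = "", ylab = "value", col = "gray60", pch = 16,
                 xlim = c(0.5, nlevels(g) + 0.5), ...)
  graphics::axis(1, at = seq_len(nlevels(g)), labels = levels(g))
  an <- sm$animals
  graphics::points(match(an$group, levels(g)), an$median, pch = 18,
                   cex = 1.6, col = "black")
  gi <- match(sm$groups$group, levels(g))
  graphics::segments(gi - 0.2, sm$groups$median, gi + 0.2, sm$groups$median,
                     lwd = 2, col = "firebrick")
  graphics::arrows(gi, sm$groups$q1, gi, sm$groups$q3, angle = 90, code = 3,
                   length = 0.06, col = "firebrick")
  invisible(sm)
}
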