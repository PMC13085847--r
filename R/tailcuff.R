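#' Ground truth for a tail-cuff pressure/flow trace
#'
#' @param true_systolic True systolic pressure in mmHg.
#' @param ramp_rate Cuff inflation/deflation rate in mmHg/s.
#' @param noise_sd Flow-signal noise sd, as a fraction of the pre-inflation
#'   flow baseline.
#' @return A `cuff_trace_truth`.
#' @export
cuff_trace_truth <- function(true_systolic, ramp_rate = 5, noise_sd = 0) {
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (ramp_rate <= 0) stopf("`ramp_rate` must be > 0")
  structure(list(true_systolic = true_systolic, ramp_rate = ramp_rate,
                 noise_sd = noise_sd),
            class = "cuff_trace_truth")
}

#' Generate a synchronized cuff-pressure / tail-flow trace
#'
#' One inflation-deflation cycle: a pre-inflation baseline segment, a
#' linear pressure up-ramp to `peak_pressure`, a brief hold, and a linear
#' down-ramp back to zero. Tail flow sits at `flow_baseline` while cuff
#' pressure is below the true systolic pressure and collapses to
#' `residual_flow * flow_baseline` while pressure is at or above it;
#' Gaussian noise of sd `truth$noise_sd * flow_baseline` is added.
#'
#' @param truth A [cuff_trace_truth()]; the ramp must cover the true
#'   systolic pressure.
#' @param sampling_rate Samples per second (Hz).
#' @param seed Integer seed.
#' @param baseline_s Pre-inflation baseline duration in seconds.
#' @param peak_pressure Peak cuff pressure in mmHg.
#' @param flow_baseline Pre-inflation flow level (arbitrary perfusion
#'   units).
#' @param residual_flow Fraction of baseline flow remaining during
#'   occlusion.
#' @return A `cuff_trace`: data.frame `time_s`, `pressure_mmHg`,
#'   `flow_au`, with the truth and sampling rate as attributes.
#' @export
gen_cuff_trace <- function(truth, sampling_rate = 20, seed = 1,
                           baseline_s = 5, peak_pressure = NULL,
                           flow_baseline = 1, residual_flow = 0.02) {
  stopifnot(inherits(truth, "cuff_trace_truth"))
  if (sampling_rate <= 0) stopf("`sampling_rate` must be > 0")
  peak_pressure <- peak_pressure %||% max(150, truth$true_systolic + 30)
  if (truth$true_systolic <= 0 || truth$true_systolic >= peak_pressure) {
    stopf("ramp [0, %g] does not cover true_systolic = %g",
          peak_pressure, truth$true_systolic)
  }
  dt <- 1 / sampling_rate
  ramp_s <- peak_pressure / truth$ramp_rate
  hold_s <- 1
  total_s <- baseline_s + 2 * ramp_s + hold_s + 2
  tt <- seq(0, total_s, by = dt)
  pressure <- numeric(length(tt))
  up <- tt > baseline_s & tt <= baseline_s + ramp_s
  pressure[up] <- (tt[up] - baseline_s) * truth$ramp_rate
  hold <- tt > baseline_s + ramp_s & tt <= baseline_s + ramp_s + hold_s
  pressure[hold] <- peak_pressure
  dn <- tt > baseline_s + ramp_s + hold_s &
    tt <= baseline_s + 2 * ramp_s + hold_s
  pressure[dn] <- peak_pressure -
    (tt[dn] - (baseline_s + ramp_s + hold_s)) * truth$ramp_rate
  pressure <- pmax(pressure, 0)
  flow <- ifelse(pressure >= truth$true_systolic,
                 residual_flow * flow_baseline, flow_baseline)
  trace <- with_seed(seed, {
    if (truth$noise_sd > 0) {
      flow <- flow + stats::rnorm(length(flow), 0,
                                  truth$noise_sd * flow_baseline)
    }
    data.frame(time_s = tt, pressure_mmHg = pressure, flow_au = flow)
  })
  attr(trace, "truth") <- truth
  attr(trace, "sampling_rate") <- sampling_rate
  class(trace) <- c("cuff_trace", "data.frame")
  trace
}

#' Extract systolic blood pressure from a cuff trace
#'
#' Smooths the flow signal with a moving average, estimates the
#' pre-inflation flow baseline, and reads off (i) the interruption
#' pressure — the cuff pressure at the first up-ramp sample where smoothed
#' flow falls below `cutoff_fraction` of baseline — and (ii) the
#' restoration pressure — the pressure at the last suppressed sample on
#' the down-ramp (flow recovers above the cutoff immediately after).
#' Systolic pressure is reported as the mean of the two; smoothing delays
#' both crossings symmetrically (later on the rising ramp, later on the
#' falling ramp), so the mean is first-order free of the smoothing bias.
#'
#' @param trace A `cuff_trace`, or any data.frame with `time_s`,
#'   `pressure_mmHg`, `flow_au`.
#' @param cutoff_fraction Flow-interruption cutoff as a fraction of the
#'   pre-inflation baseline (default 0.10).
#' @param smooth_window Moving-average window in seconds (default 0.5).
#' @return List with `interruption_pressure`, `restoration_pressure`,
#'   `systolic` (mmHg).
#' @export
systolic_from_trace <- function(trace, cutoff_fraction = 0.10,
                                smooth_window = 0.5) {
  need <- c("time_s", "pressure_mmHg", "flow_au")
  if (!all(need %in% names(trace))) {
    stopf("trace needs columns %s", paste(need, collapse = ", "))
  }
  tt <- trace$time_s; p <- trace$pressure_mmHg; f <- trace$flow_au
  if (is.unsorted(tt, strictly = TRUE)) stopf("time must be strictly increasing")
  dt <- stats::median(diff(tt))
  k <- max(1L, 2L * floor(smooth_window / dt / 2) + 1L)
  fs <- if (k > 1) stats::filter(f, rep(1 / k, k), sides = 2) else f
  fs <- as.numeric(fs)
  # fill the filter's NA borders with the raw signal
  fs[is.na(fs)] <- f[is.na(fs)]
  pre <- which(p <= 0 & seq_along(p) < which.max(p > 0)[1])
  if (!length(pre) || !any(p > 0)) {
    stopf("no pre-inflation baseline segment (pressure never zero before the ramp)")
  }
  baseline <- mean(f[pre])
  if (!is.finite(baseline) || baseline <= 0) {
    stopf("flow baseline not estimable from the pre-inflation segment")
  }
  cutoff <- cutoff_fraction * baseline
  ipk <- which.max(p)
  up_idx <- seq_len(ipk)
  dn_idx <- ipk:length(p)
  i_int <- up_idx[which(fs[up_idx] < cutoff)[1]]
  if (is.na(i_int)) stopf("flow never interrupted on the up-ramp")
  below_dn <- dn_idx[fs[dn_idx] < cutoff]
  if (!length(below_dn)) stopf("flow never interrupted on the down-ramp")
  i_res <- max(below_dn) # last suppressed sample before sustained recovery
  list(interruption_pressure = p[i_int],
       restoration_pressure = p[i_res],
       systolic = (p[i_int] + p[i_res]) / 2)
}

#' Average repeated cuff-cycle measurements
#'
#' The study measures twice per session; this averages the per-cycle
#' systolic estimates.
#'
#' @param results List of results from [systolic_from_trace()].
#' @return Mean systolic pressure in mmHg.
#' @export
average_systolic <- function(results) {
  mean(vapply(results, function(r) r$systolic, 0))
}
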