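#' Ground truth for a serial-section infarct series
#'
#' @param true_infarct_volume True lesion volume in mm^3 (>= 0).
#' @param edema_factor Multiplicative inflation applied to infarcted
#'   ipsilateral tissue (>= 1; 1 = no edema).
#' @param spacing_mm Distance between analyzed sections in mm (study:
#'   0.5 mm).
#' @param n_sections Number of analyzed sections (study: 10).
#' @param shape `"ellipsoid"` (parabolic area profile, the shape of an
#'   ellipsoidal lesion cut by parallel planes) or `"uniform"`.
#' @return A `section_series_truth`.
#' @export
section_series_truth <- function(true_infarct_volume, edema_factor = 1,
                                 spacing_mm = 0.5, n_sections = 10,
                                 shape = c("ellipsoid", "uniform")) {
  shape <- match.arg(shape)
  if (true_infarct_volume < 0) stopf("`true_infarct_volume` must be >= 0")
  if (edema_factor < 1) stopf("`edema_factor` must be >= 1")
  if (spacing_mm <= 0) stopf("`spacing_mm` must be > 0")
  if (n_sections < 1) stopf("`n_sections` must be >= 1")
  structure(list(true_infarct_volume = true_infarct_volume,
                 edema_factor = edema_factor, spacing_mm = spacing_mm,
                 n_sections = as.integer(n_sections), shape = shape),
            class = "section_series_truth")
}

infarct_area_profile <- function(truth) {
  n <- truth$n_sections
  dz <- truth$spacing_mm
  if (truth$true_infarct_volume == 0) return(rep(0, n))
  if (truth$shape == "uniform") {
    rep(truth$true_infarct_volume / (n * dz), n)
  } else {
    # ellipsoidal lesion spanning the sampled extent; sections at slab
    # midpoints. V = A_max * 4c/3 for a(z) = A_max (1 - (z/c)^2).
    c_half <- n * dz / 2
    a_max <- 3 * truth$true_infarct_volume / (4 * c_half)
    z <- -c_half + (seq_len(n) - 0.5) * dz
    pmax(a_max * (1 - (z / c_half)^2), 0)
  }
}

#' Generate serial-section area records with edema inflation
#'
#' Produces per-section contralateral hemisphere areas and ipsilateral
#' non-infarcted areas consistent with the true infarct volume under the
#' sum-of-areas-times-spacing volume rule. Edema inflates only the
#' infarcted ipsilateral tissue (recorded in `ipsilateral_total_area`), so
#' the edema-corrected (Swanson) adjusted area — contralateral minus
#' ipsilateral non-infarcted — is unaffected by the edema factor by
#' construction.
#'
#' @param truth A [section_series_truth()].
#' @param hemisphere_area Healthy hemisphere section area in mm^2; must
#'   exceed the largest per-section infarct area.
#' @param seed Integer seed (used when `noise_sd > 0`).
#' @param noise_sd Gaussian measurement noise sd (mm^2) added to the
#'   contralateral and ipsilateral non-infarct areas.
#' @return A `section_area_records` data.frame: `section_index`,
#'   `contralateral_area`, `ipsilateral_noninfarct_area`,
#'   `ipsilateral_total_area`, `spacing_to_next_mm`; the truth is attached
#'   as attribute `truth`.
#' @export
gen_section_series <- function(truth, hemisphere_area = 25, seed = 1,
                               noise_sd = 0) {
  stopifnot(inherits(truth, "section_series_truth"))
  a <- infarct_area_profile(truth)
  if (max(a) >= hemisphere_area) {
    stopf("infarct area (max %.2f mm^2) exceeds the hemisphere (%.2f mm^2)",
          max(a), hemisphere_area)
  }
  n <- truth$n_sections
  with_seed(seed, {
    contra <- rep(hemisphere_area, n)
    noninf <- hemisphere_area - a
    if (noise_sd > 0) {
      contra <- contra + stats::rnorm(n, 0, noise_sd)
      noninf <- pmax(noninf + stats::rnorm(n, 0, noise_sd), 0)
    }
    df <- data.frame(section_index = seq_len(n),
                     contralateral_area = contra,
                     ipsilateral_noninfarct_area = noninf,
                     ipsilateral_total_area = noninf + truth$edema_factor * a,
                     spacing_to_next_mm = truth$spacing_mm)
    attr(df, "truth") <- truth
    class(df) <- c("section_area_records", "data.frame")
    df
  })
}

#' Edema-corrected (Swanson) adjusted infarct area
#'
#' Adjusted infarct area = contralateral hemisphere area minus the
#' non-infarcted area of the ipsilateral hemisphere. Because edema swells
#' the infarcted tissue but not the surviving ipsilateral tissue, this
#' subtraction removes the edema artifact. Negative values (possible with
#' measurement noise) are returned as-is with a warning.
#'
#' @param records A data.frame with `contralateral_area` and
#'   `ipsilateral_noninfarct_area` (mm^2), e.g. from
#'   [gen_section_series()] or read from a CSV.
#' @return Numeric vector of adjusted areas (mm^2).
#' @export
adjusted_infarct_area <- function(records) {
  need <- c("contralateral_area", "ipsilateral_noninfarct_area")
  if (!all(need %in% names(records))) {
    stopf("records need columns %s", paste(need, collapse = ", "))
  }
  adj <- records$contralateral_area - records$ipsilateral_noninfarct_area
  if (any(adj < 0)) {
    warning(sprintf("%d negative adjusted area(s); returned as-is",
                    sum(adj < 0)), call. = FALSE)
  }
  adj
}

#' Infarct volume from serial sections
#'
#' Volume = sum of adjusted infarct areas times the inter-section spacing
#' (0.5 mm in the study design: 10 sections spanning 5 mm
#' anteroposteriorly, which makes this identical to mean area times the
#' 5 mm extent).
#'
#' @param records A data.frame as in [adjusted_infarct_area()]; spacing is
#'   taken from `spacing_to_next_mm` if present.
#' @param spacing_mm Inter-section spacing in mm (default 0.5), used when
#'   the records carry none.
#' @return Volume in mm^3.
#' @export
infarct_volume <- function(records, spacing_mm = 0.5) {
  if (nrow(records) < 1) stopf("no section records")
  sp <- if ("spacing_to_next_mm" %in% names(records)) {
    records$spacing_to_next_mm
  } else rep(spacing_mm, nrow(records))
  if (length(unique(round(sp, 9))) > 1) {
    warning("non-uniform section spacing; using per-section values",
            call. = FALSE)
  }
  sum(adjusted_infarct_area(records) * sp)
}
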