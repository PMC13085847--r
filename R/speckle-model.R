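#' Single-exposure speckle contrast forward model
#'
#' Speckle contrast as a function of the ratio of camera exposure time to
#' speckle decorrelation time, `x = T / tau_c`, under the usual
#' negative-exponential field-correlation model with a coherence factor
#' `beta`:
#' \deqn{K(x)^2 = \beta \, \frac{e^{-2x} - 1 + 2x}{2x^2}.}
#' `K` decreases monotonically from `sqrt(beta)` (static scatterers,
#' `x -> 0`) towards 0 (fast flow). For `x >= 100` the model is within a
#' few percent of the simple asymptote `K^2 ~ beta / x`.
#'
#' @param x Non-negative numeric vector, exposure time over correlation time.
#' @param beta Coherence factor in (0, 1].
#' @return Speckle contrast values, same length as `x`.
#' @seealso [ict_from_contrast()] for the inverse.
#' @export
#' @examples
#' speckle_contrast(1)      # ~0.7534
#' speckle_contrast(0)      # sqrt(beta) = 1
speckle_contrast <- function(x, beta = 1) {
  check_beta(beta)
  if (any(!is.finite(x) & !is.na(x)) || any(x < 0, na.rm = TRUE)) {
    stopf("`x` must be finite and non-negative")
  }
  sqrt(beta * k2_reduced(x))
}

# (exp(-2x) - 1 + 2x) / (2 x^2), with a series expansion near 0.
k2_reduced <- function(x) {
  out <- x
  small <- !is.na(x) & x < 1e-4
  xs <- x[small]
  out[small] <- 1 - (2 / 3) * xs + (1 / 3) * xs^2 - (2 / 15) * xs^3
  xl <- x[!small & !is.na(x)]
  out[!small & !is.na(x)] <- (exp(-2 * xl) - 1 + 2 * xl) / (2 * xl^2)
  out
}

# d/dx of k2_reduced
k2_reduced_deriv <- function(x) {
  out <- x
  small <- !is.na(x) & x < 1e-4
  xs <- x[small]
  out[small] <- -(2 / 3) + (2 / 3) * xs - (2 / 5) * xs^2
  xl <- x[!small & !is.na(x)]
  out[!small & !is.na(x)] <-
    (1 - exp(-2 * xl)) / xl^2 - (exp(-2 * xl) - 1 + 2 * xl) / xl^3
  out
}

check_beta <- function(beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0 || beta > 1) {
    stopf("`beta` must be a single value in (0, 1]")
  }
  invisible(beta)
}

# Invert K^2/beta = k2_reduced(x) for x >= 0. Vectorized: log-log
# interpolation on a precomputed grid, refined by Newton iterations.
solve_speckle_x <- function(u) {
  x <- rep(NA_real_, length(u))
  ok <- !is.na(u)
  x[ok & u >= 1] <- 0
  todo <- ok & u < 1 & u > 0
  if (any(todo)) {
    ut <- u[todo]
    grid <- speckle_inversion_grid()
    lx <- stats::approx(grid$lu, grid$lx, xout = log(ut), rule = 2)$y
    xi <- exp(lx)
    # Newton on f(x) = k2_reduced(x) - u in log space for positivity
    for (i in 1:8) {
      f <- k2_reduced(xi) - ut
      d <- k2_reduced_deriv(xi)
      step <- f / (d * xi) # derivative wrt log x
      step <- pmax(pmin(step, 2), -2)
      xi <- xi * exp(-step)
    }
    x[todo] <- xi
  }
  x[ok & u <= 0] <- Inf # K = 0: decorrelation faster than any exposure
  x
}

speckle_grid_env <- new.env(parent = emptyenv())

speckle_inversion_grid <- function() {
  if (is.null(speckle_grid_env$grid)) {
    lx <- seq(log(1e-8), log(1e12), length.out = 4096)
    lu <- log(k2_reduced(exp(lx)))
    speckle_grid_env$grid <- list(lu = rev(lu), lx = rev(lx))
  }
  speckle_grid_env$grid
}

#' Invert speckle contrast to inverse correlation time
#'
#' Solves the single-exposure forward model (see [speckle_contrast()]) for
#' `x = T / tau_c` at each contrast value and returns the inverse
#' correlation time `ICT = 1 / tau_c = x / T`, taking the camera exposure
#' time into account. Contrast at or above `sqrt(beta)` (static scatterers,
#' or noise pushing the estimate past the model ceiling) maps to `ICT = 0`;
#' the number of such clamped values is reported via the `"n_clamped"`
#' attribute. `NA` values propagate.
#'
#' @param k Speckle contrast values (vector, matrix or array).
#' @param exposure Camera exposure time in seconds (e.g. `5e-3`).
#' @param beta Coherence factor in (0, 1].
#' @return Inverse correlation times in 1/s, same shape as `k`, with
#'   attribute `n_clamped`.
#' @export
#' @examples
#' ict_from_contrast(0.7534372, exposure = 5e-3)  # ~200 1/s
ict_from_contrast <- function(k, exposure, beta = 1) {
  if (length(exposure) != 1L || !is.finite(exposure) || exposure <= 0) {
    stopf("`exposure` must be a single positive number (seconds)")
  }
  check_beta(beta)
  u <- k^2 / beta
  clamped <- sum(!is.na(u) & u >= 1 & k > 0)
  x <- solve_speckle_x(as.numeric(u))
  ict <- x / exposure
  ict[is.infinite(ict)] <- NA_real_ # K = 0 carries no finite estimate
  out <- k
  out[] <- ict
  attr(out, "n_clamped") <- clamped
  out
}
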