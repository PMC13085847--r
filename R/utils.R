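#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_odd_window <- function(window, dim = NULL) {
  if (length(window) != 1L || !is.finite(window) || window < 3 ||
      window %% 2 != 1) {
    stopf("`window` must be a single odd integer >= 3 (got %s)",
          paste(window, collapse = ","))
  }
  if (!is.null(dim) && window >= min(dim)) {
    stopf("`window` (%d) must be smaller than the image (%d x %d)",
          window, dim[1], dim[2])
  }
  invisible(as.integer(window))
}

# Box-window sum with truncated (shrinking) windows at the borders.
box_sum <- function(x, radius) {
  n1 <- nrow(x); n2 <- ncol(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  hi <- pmin(seq_len(n1) + radius, n1) + 1L
  lo <- pmax(seq_len(n1) - radius, 1L)
  xs <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(0, t(apply(xs, 1, cumsum)))
  hj <- pmin(seq_len(n2) + radius, n2) + 1L
  lj <- pmax(seq_len(n2) - radius, 1L)
  cs2[, hj, drop = FALSE] - cs2[, lj, drop = FALSE]
}

box_count <- function(dim, radius) {
  n1 <- dim[1]; n2 <- dim[2]
  c1 <- pmin(seq_len(n1) + radius, n1) - pmax(seq_len(n1) - radius, 1L) + 1L
  c2 <- pmin(seq_len(n2) + radius, n2) - pmax(seq_len(n2) - radius, 1L) + 1L
  outer(c1, c2)
}

# Local mean and population (denominator N) standard deviation over a
# square window. Borders use the truncated window.
local_mean_sd <- function(x, window) {
  r <- (window - 1L) %/% 2L
  n <- box_count(dim(x), r)
  m <- box_sum(x, r) / n
  v <- box_sum(x * x, r) / n - m * m
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# Unit-variance, zero-mean noise texture with period `window` in both
# dimensions: a random permutation of the standardized exponential
# quantile multiset, tiled with a random toroidal shift. Every square
# window of size `window` then contains exactly one full period, so its
# sample mean and population sd are exactly 0 and 1 — the window contrast
# of mu * (1 + K * Z) equals K exactly away from the truncated borders.
speckle_noise_field <- function(nr, nc, window) {
  n <- window * window
  q <- stats::qexp((seq_len(n) - 0.5) / n)
  z <- (q - mean(q)) / sqrt(mean((q - mean(q))^2))
  zm <- matrix(sample(z), window, window)
  oi <- sample.int(window, 1)
  oj <- sample.int(window, 1)
  zm[((seq_len(nr) + oi) %% window) + 1L,
     ((seq_len(nc) + oj) %% window) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
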