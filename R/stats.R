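#' Normality gate (Shapiro-Wilk)
#'
#' Tests a sample for normality and recommends the downstream test family.
#' The study routes all non-normally distributed data to nonparametric
#' tests; everything downstream in this package is nonparametric, so the
#' recommendation is informational.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level for the gate.
#' @return List with `decision` (`"normal"` / `"non-normal"`), `p_value`,
#'   `degenerate` (constant sample) and `recommendation`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stopf("normality test needs n >= 3")
  if (stats::sd(values) == 0) {
    return(list(decision = "non-normal", p_value = NA_real_,
                degenerate = TRUE, recommendation = "nonparametric"))
  }
  p <- stats::shapiro.test(values)$p.value
  decision <- if (p >= alpha) "normal" else "non-normal"
  list(decision = decision, p_value = p, degenerate = FALSE,
       recommendation = if (decision == "normal") "parametric (not provided here)"
                        else "nonparametric")
}

# U statistic of sample a vs b: number of (a_i, b_j) pairs with a_i > b_j,
# ties counting one half. Computed from rank sums.
u_statistic <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(m)])
  ua <- ra - m * (m + 1) / 2
  c(ua = ua, ub = m * n - ua)
}

#' Mann-Whitney U test (exact by enumeration, or tie-corrected normal)
#'
#' Two-sided rank-sum test for two independent groups. In exact mode the
#' null distribution of U is obtained by full enumeration of all
#' `choose(m + n, m)` group assignments of the pooled values (valid with
#' ties; limited to m + n <= 12); the two-sided p value doubles the
#' smaller tail (capped at 1). In asymptotic mode a tie-corrected normal
#' approximation without continuity correction is used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param mode `"auto"` (exact when m + n <= 12), `"exact"`, or
#'   `"asymptotic"`.
#' @return List with `statistic` (U = min of the two group U's), `U_a`,
#'   `U_b`, `p_value`, `mode`.
#' @export
mwu_test <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  m <- length(a); n <- length(b)
  if (mode == "auto") mode <- if (m + n <= 12) "exact" else "asymptotic"
  u <- u_statistic(a, b)
  if (mode == "exact") {
    if (m + n > 12) stopf("exact mode limited to m + n <= 12")
    pooled <- c(a, b)
    combs <- utils::combn(m + n, m)
    r <- rank(pooled)
    ua_null <- apply(combs, 2, function(idx) {
      sum(r[idx]) - m * (m + 1) / 2
    })
    p <- 2 * min(mean(ua_null <= u["ua"]), mean(ua_null >= u["ua"]))
    p <- min(p, 1)
  } else {
    N <- m + n
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u["ua"] - m * n / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(statistic = unname(min(u)), U_a = unname(u["ua"]),
       U_b = unname(u["ub"]), p_value = unname(p), mode = mode)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' @param groups List of >= 3 non-empty numeric vectors.
#' @return List with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stopf("need >= 3 groups (use mwu_test() for two)")
  }
  if (any(vapply(groups, length, 0L) == 0)) stopf("groups must be non-empty")
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- if (corr > 0) h / corr else 0
  df <- length(groups) - 1
  list(statistic = h, df = df,
       p_value = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are removed; exact p (enumeration of all 2^n sign
#' patterns of the observed midranks) for n <= 12, otherwise a
#' tie-corrected normal approximation.
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @return List with `statistic` (W = min of positive/negative rank sums),
#'   `W_plus`, `W_minus`, `p_value`, `n_used`, `mode`.
#' @export
wilcoxon_signed <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stopf("unequal lengths")
  d <- paired_a - paired_b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n < 3) stopf("need >= 3 non-zero differences (all-zero is degenerate)")
  r <- rank(abs(d))
  wp <- sum(r[d > 0]); wm <- sum(r[d < 0])
  if (n <= 12) {
    mode <- "exact"
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.numeric(signs %*% r)
    p <- 2 * min(mean(w_null <= wp), mean(w_null >= wp))
    p <- min(p, 1)
  } else {
    mode <- "asymptotic"
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (wp - n * (n + 1) / 4) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = min(wp, wm), W_plus = wp, W_minus = wm,
       p_value = p, n_used = n, mode = mode)
}

#' Pearson correlation and ordinary least-squares line
#'
#' @param x,y Numeric vectors, n >= 3, both non-constant.
#' @return List with `R`, `R2`, `slope`, `intercept`, `p_value` (two-sided
#'   t transform), `n`.
#' @export
pearson_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  r <- stats::cor(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  list(R = r, R2 = r^2, slope = slope, intercept = intercept,
       p_value = p, n = n)
}

#' Superplot-style group summary
#'
#' Group-level median and interquartile range (Q1-Q3, type-7 linear
#' interpolation quantiles) over all values, plus per-animal medians for
#' superplot overlays that distinguish animal-level replicates from
#' section-level measurements.
#'
#' @param values Numeric vector, or a data.frame with columns `value`,
#'   `group`, `animal_id`.
#' @param group,animal_id Vectors parallel to `values` (ignored when
#'   `values` is a data.frame).
#' @return List with `groups` (data.frame: `group`, `median`, `q1`, `q3`,
#'   `n`, `n_animals`) and `animals` (data.frame: `group`, `animal_id`,
#'   `median`, `n`).
#' @export
superplot_summary <- function(values, group = NULL, animal_id = NULL) {
  if (is.data.frame(values)) {
    df <- values
    if (!all(c("value", "group") %in% names(df))) {
      stopf("data.frame input needs columns value, group")
    }
    if (!nrow(df)) stopf("no data")
    if (!"animal_id" %in% names(df)) df$animal_id <- "a1"
  } else {
    if (is.null(group)) group <- "all"
    if (is.null(animal_id)) animal_id <- "a1"
    df <- data.frame(value = values,
                     group = rep(group, length.out = length(values)),
                     animal_id = rep(animal_id, length.out = length(values)))
  }
  if (!nrow(df)) stopf("no data")
  q <- function(v, p) unname(stats::quantile(v, p, type = 7))
  groups <- do.call(rbind, lapply(split(df, df$group), function(dd) {
    data.frame(group = dd$group[1],
               median = stats::median(dd$value),
               q1 = q(dd$value, 0.25), q3 = q(dd$value, 0.75),
               n = nrow(dd), n_animals = length(unique(dd$animal_id)))
  }))
  animals <- do.call(rbind, lapply(
    split(df, list(df$group, df$animal_id), drop = TRUE), function(dd) {
      data.frame(group = dd$group[1], animal_id = dd$animal_id[1],
                 median = stats::median(dd$value), n = nrow(dd))
    }))
  rownames(groups) <- rownames(animals) <- NULL
  list(groups = groups, animals = animals)
}

#' Lactate dose arithmetic
#'
#' Systemic dose in mg per kg body weight delivered by injecting
#' `volume_uL_per_g` microliters per gram of a solution of concentration
#' `conc_mmol_per_L` of a compound with molar mass `molar_mass`: the
#' study's 5 uL/g of 200 mmol/L sodium lactate (112.06 g/mol) is about
#' 112 mg/kg.
#'
#' @param volume_uL_per_g Injected volume per body weight, uL/g.
#' @param conc_mmol_per_L Solution concentration, mmol/L.
#' @param molar_mass Molar mass, g/mol.
#' @return Dose in mg/kg.
#' @export
solution_dose_mg_per_kg <- function(volume_uL_per_g = 5,
                                    conc_mmol_per_L = 200,
                                    molar_mass = 112.06) {
  volume_uL_per_g * conc_mmol_per_L * molar_mass / 1000
}
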