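test_that("normality gate routes gross departures and respects preconditions", {
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  const <- normality_gate(rep(5, 10))
  expect_equal(const$decision, "non-normal")
  expect_true(const$degenerate)
  # two-point discretized sample is grossly non-normal
  set.seed(1)
  two <- round(stats::runif(50))
  expect_equal(normality_gate(two)$decision, "non-normal")
  # normal draws pass the gate at about the nominal rate
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(stats::rnorm(500))$decision == "normal"
  }, TRUE)
  expect_gte(mean(ok), 0.90)
})

test_that("Mann-Whitney exact enumeration matches hand counts and wilcox.test", {
  r <- mwu_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 * 1/20 over all C(6,3) assignments
  expect_equal(r$p_value, wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  # identical multisets -> p = 1 by symmetry
  expect_equal(mwu_test(c(1, 2, 3), c(1, 2, 3), mode = "exact")$p_value, 1)
  # cross-check exact p against wilcox.test on random tie-free samples
  for (s in 1:5) {
    set.seed(s)
    a <- stats::rnorm(5); b <- stats::rnorm(6)
    expect_equal(mwu_test(a, b, mode = "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # exact vs tie-corrected asymptotic agree within 0.02 at 6 vs 6
  set.seed(42)
  a <- stats::rnorm(6); b <- stats::rnorm(6) + 1
  expect_lt(abs(mwu_test(a, b, mode = "exact")$p_value -
                mwu_test(a, b, mode = "asymptotic")$p_value), 0.02)
  expect_error(mwu_test(numeric(0), 1:3), "non-empty")
  expect_error(mwu_test(1:10, 1:10, mode = "exact"), "exact mode")
})

test_that("exact MWU attainable size at n = 5 vs 5 equals the enumerated value", {
  # discreteness: at alpha = 0.05 the exact two-sided test rejects iff
  # U <= 2, so its true size is 2 * P(U <= 2) = 8/252 (enumeration oracle)
  combs <- utils::combn(10, 5)
  r <- 1:10
  ua <- apply(combs, 2, function(idx) sum(r[idx]) - 15)
  u <- pmin(ua, 25 - ua)
  pvals <- vapply(unique(u), function(uu) {
    2 * min(mean(ua <= uu), mean(ua >= uu))
  }, 0)
  size_theory <- mean(vapply(ua, function(uu) {
    2 * min(mean(ua <= uu), mean(ua >= uu)) <= 0.05
  }, TRUE))
  expect_equal(size_theory, 8 / 252)
  # simulated null rejection rate matches the enumerated size
  set.seed(99)
  rej <- vapply(1:2000, function(i) {
    x <- stats::rnorm(5); y <- stats::rnorm(5)
    mwu_test(x, y, mode = "exact")$p_value <= 0.05
  }, TRUE)
  mc_se <- sqrt(size_theory * (1 - size_theory) / 2000)
  expect_lt(abs(mean(rej) - size_theory), 4 * mc_se)
})

test_that("Kruskal-Wallis H matches the rank formula and kruskal.test", {
  # three identical groups -> H = 0
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))$statistic, 0)
  # rank-formula oracle for [1,2], [3,4], [5,6]:
  # H = 12/(6*7) * (3^2 + 7^2 + 11^2)/2 - 3*7 = 32/7
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(r$statistic,
               unname(kruskal.test(list(c(1, 2), c(3, 4), c(5, 6)))$statistic),
               tolerance = 1e-12)
  # permuting group order leaves H unchanged
  expect_equal(kruskal_wallis(list(c(5, 6), c(1, 2), c(3, 4)))$statistic,
               r$statistic)
  # tie correction cross-checked against kruskal.test
  g <- list(c(1, 1, 2), c(2, 3, 3), c(4, 4, 5))
  expect_equal(kruskal_wallis(g)$statistic,
               unname(kruskal.test(g)$statistic), tolerance = 1e-12)
  expect_equal(kruskal_wallis(g)$p_value,
               kruskal.test(g)$p.value, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "mwu_test")
})

test_that("Wilcoxon signed-rank: enumeration oracle and symmetry", {
  a <- c(1, 2, 3, 4, 5)
  r <- wilcoxon_signed(a, a + 3)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 32) # all-negative signs among 2^5 patterns
  # all differences zero is degenerate
  expect_error(wilcoxon_signed(a, a), "degenerate|>= 3")
  # swapping the samples leaves p unchanged
  set.seed(3)
  x <- stats::rnorm(8); y <- x + stats::rnorm(8)
  expect_equal(wilcoxon_signed(x, y)$p_value, wilcoxon_signed(y, x)$p_value)
  # cross-check against wilcox.test for tie-free differences
  for (s in 1:5) {
    set.seed(s)
    x <- stats::rnorm(7); y <- x + stats::rnorm(7)
    expect_equal(wilcoxon_signed(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Pearson correlation, regression line and printed R/R2 consistency", {
  x <- 1:10
  r <- pearson_regression(x, 2 * x + 1)
  expect_equal(r$R, 1)
  expect_equal(r$R2, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  # R2 equals R^2 to machine precision on arbitrary data
  set.seed(8)
  xx <- stats::rnorm(30); yy <- xx + stats::rnorm(30)
  rr <- pearson_regression(xx, yy)
  expect_identical(rr$R2, rr$R^2)
  # the study's printed pairs are self-consistent
  expect_equal(round(0.976^2, 3), 0.953)
  expect_equal(round((-0.969)^2, 3), 0.939)
  expect_equal(round((-0.6551)^2, 4), 0.4292, tolerance = 1e-3)
  # cross-check slope/p against lm/cor.test
  fit <- stats::lm(yy ~ xx)
  expect_equal(rr$slope, unname(stats::coef(fit)[2]), tolerance = 1e-12)
  expect_equal(rr$p_value, stats::cor.test(xx, yy)$p.value, tolerance = 1e-12)
  expect_error(pearson_regression(rep(1, 5), 1:5), "constant")
})

test_that("rank statistics are invariant to strictly monotone transforms", {
  set.seed(10)
  a <- stats::runif(6); b <- stats::runif(7)
  f <- function(v) exp(3 * v) - 1
  expect_equal(mwu_test(a, b)$p_value, mwu_test(f(a), f(b))$p_value)
  g <- list(stats::runif(4), stats::runif(5), stats::runif(4))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, f))$statistic)
})

test_that("superplot summaries use type-7 quartiles and per-animal medians", {
  s <- superplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$groups$median, 3)
  expect_equal(s$groups$q1, 2)
  expect_equal(s$groups$q3, 4)
  one <- superplot_summary(7)
  expect_equal(unlist(one$groups[c("median", "q1", "q3")]),
               c(median = 7, q1 = 7, q3 = 7))
  df <- data.frame(value = c(1, 3, 5), group = "g",
                   animal_id = c("A", "A", "B"))
  s2 <- superplot_summary(df)
  am <- s2$animals[order(s2$animals$animal_id), ]
  expect_equal(am$median, c(2, 5))
  expect_equal(s2$groups$n_animals, 2)
  expect_error(superplot_summary(data.frame(value = numeric(0),
                                            group = character(0))), "no data")
})
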