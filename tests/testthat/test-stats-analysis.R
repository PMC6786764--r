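test_that("Spearman r ranks, correlates, and handles monotone extremes", {
  expect_equal(spearman_r(1:10, (1:10)^3), 1)
  expect_equal(spearman_r(1:10, rev(1:10)), -1)
  expect_equal(spearman_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_r(1:5, rep(2, 5)), "constant")
  expect_error(spearman_r(1:2, 1:2), "3 observations")
  # agreement with the reference implementation, including ties
  set.seed(6)
  for (k in 1:10) {
    x <- sample(1:8, 15, replace = TRUE)
    y <- x + rnorm(15)
    expect_equal(spearman_r(x, y),
                 suppressWarnings(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- runif(20); y <- runif(20)
  r0 <- spearman_r(x, y)
  expect_equal(spearman_r(exp(x), y), r0)
  expect_equal(spearman_r(x, y^3 + 2 * y), r0)
  expect_equal(spearman_r(log(x + 1), atan(y)), r0)
})

test_that("the correlation t statistic follows r sqrt(n-2)/sqrt(1-r^2)", {
  expect_equal(t_from_r(0, 10), 0)
  expect_equal(t_from_r(0.93, 23), 11.58, tolerance = 0.05)
  expect_equal(t_from_r(0.89, 11), 5.87, tolerance = 0.05)
  expect_warning(t_inf <- t_from_r(1, 5), "infinite")
  expect_identical(t_inf, Inf)
  expect_error(t_from_r(0.5, 2), "n >= 3")
  # identity t^2 = (n-2) r^2 / (1-r^2) on random inputs
  set.seed(8)
  for (k in 1:20) {
    r <- runif(1, -0.99, 0.99); n <- sample(3:50, 1)
    expect_equal(t_from_r(r, n)^2, (n - 2) * r^2 / (1 - r^2),
                 tolerance = 1e-12)
  }
})

test_that("critical values reproduce the tabulated t and chi-squared entries", {
  expect_equal(round(critical_value("t", 0.05, 21), 3), 2.080)
  expect_equal(round(critical_value("t", 0.05, 6), 3), 2.447)
  expect_equal(round(critical_value("t", 0.05, 9), 3), 2.262)
  expect_equal(round(critical_value("chi2", 0.05, 1), 2), 3.84)
  expect_equal(round(critical_value("chi2", 0.05, 2), 2), 5.99)
  # two-sided t criticals decrease with df towards the normal 1.96
  cv <- vapply(c(5, 10, 30, 100, 1000), function(d)
    critical_value("t", 0.05, d), numeric(1))
  expect_true(all(diff(cv) < 0))
  expect_equal(cv[5], 1.96, tolerance = 1e-2)
  expect_error(critical_value("t", 1.2, 5), "alpha")
})

test_that("Kruskal-Wallis H follows the rank-sum formula", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4))), 2.4)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  # equality with the reference implementation on tie-free data
  set.seed(9)
  for (k in 1:5) {
    g <- list(rnorm(6), rnorm(8), rnorm(5))
    expect_equal(kruskal_wallis(g),
                 unname(stats::kruskal.test(g)$statistic), tolerance = 1e-12)
  }
  # tie correction matches the reference implementation under ties
  gt <- list(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_equal(kruskal_wallis(gt, tie_correct = TRUE),
               unname(stats::kruskal.test(gt)$statistic), tolerance = 1e-12)
  expect_lt(kruskal_wallis(gt), kruskal_wallis(gt, tie_correct = TRUE))
})

test_that("root fits recover the proportionality coefficient", {
  D <- c(0.2, 0.5, 1, 2, 4)
  s <- dose_cnr_series("toy", D, 2 * sqrt(D))
  expect_equal(fit_root(s)$a, 2, tolerance = 1e-12)
  # scale equivariance
  s2 <- dose_cnr_series("toy", D, 2 * 2 * sqrt(D))
  expect_equal(fit_root(s2)$a, 4, tolerance = 1e-12)
  expect_error(fit_root(dose_cnr_series("toy", D[1:2], c(1, 2))), "3 points")
  expect_error(dose_cnr_series("toy", c(0, 1, 2), c(1, 2, 3)), "positive")
})

test_that("the root-fit estimator is unbiased under Gaussian noise", {
  set.seed(10)
  a_true <- 30
  D <- seq(0.2, 4, length.out = 10)
  est <- replicate(200, fit_root(dose_cnr_series(
    "sim", D, a_true * sqrt(D) + rnorm(10)))$a)
  expect_equal(mean(est), a_true, tolerance = 0.5 / a_true)
})

test_that("free-exponent power fit finds the exponent of exact data", {
  D <- c(0.3, 0.6, 1.2, 2.4)
  f <- fit_power(dose_cnr_series("toy", D, 5 * D^0.5))
  expect_equal(f$b, 0.5, tolerance = 1e-9)
  expect_equal(f$a, 5, tolerance = 1e-9)
})

test_that("matched-CNR dose readout inverts the root model", {
  expect_equal(dose_at_cnr(2, 2), 1)
  expect_equal(dose_at_cnr(30, 15), 0.25)
  # dose ratio between methods is (a2/a1)^2, independent of the target
  a1 <- 20; a2 <- 20 * sqrt(2.5)
  for (target in c(5, 10, 25))
    expect_equal(dose_at_cnr(a1, target) / dose_at_cnr(a2, target), 2.5,
                 tolerance = 1e-12)
  expect_error(dose_at_cnr(-1, 5), "positive")
  expect_error(dose_at_cnr(2, 0), "positive")
})

test_that("stats_report assembles decisions consistently", {
  set.seed(12)
  D <- seq(0.2, 2.5, length.out = 8)
  sl <- list(a = dose_cnr_series("a", D, 10 * sqrt(D) + rnorm(8, sd = 0.4)),
             b = dose_cnr_series("b", D, 4 * sqrt(D) + rnorm(8, sd = 0.4)))
  rep <- suppressWarnings(stats_report(sl))  # near-perfect monotone series may hit r = 1
  expect_equal(nrow(rep$per_series), 2)
  expect_true(all(rep$per_series$reject ==
                  (abs(rep$per_series$t_calc) > rep$per_series$t_crit)))
  expect_equal(rep$kruskal$df, 1)
  expect_equal(rep$kruskal$reject, rep$kruskal$H > rep$kruskal$chi2_crit)
})

test_that("dose-CNR series round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(method = rep(c("kes", "md"), each = 3),
                   mgd_mgy = c(0.2, 0.5, 1, 0.2, 0.5, 1),
                   cnr = c(5, 8, 11, 6, 9, 13))
  utils::write.csv(df, path, row.names = FALSE)
  sl <- read_dose_cnr_csv(path)
  expect_named(sl, c("kes", "md"))
  expect_equal(sl$md$points$cnr, c(6, 9, 13))
  expect_equal(sl$kes$n, 3)
})
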