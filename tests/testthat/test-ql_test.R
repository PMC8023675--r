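test_that("quasi_dispersion is deviance over residual df with a floor", {
  f <- list(deviance = 12, df_residual = 6L)
  expect_equal(quasi_dispersion(f), 2)
  expect_equal(quasi_dispersion(list(deviance = 0, df_residual = 4L)), 1e-8)
  expect_error(quasi_dispersion(list(deviance = 1, df_residual = 0L)),
               "residual degrees of freedom")
  # simulated Poisson data fitted at the true model: mean sigma^2 near 1
  set.seed(17)
  n <- 50
  X <- matrix(1, n, 1)
  s2 <- replicate(500, {
    y <- rpois(n, 20)
    quasi_dispersion(fit_beta(y, X, theta = 0))
  })
  se <- sd(s2) / sqrt(length(s2))
  expect_lt(abs(mean(s2) - 1), 3 * se + 0.02)
})

test_that("trigamma inversion recovers its argument on a grid", {
  for (x in c(1, 5, 20)) {
    expect_equal(trigamma_inverse(trigamma(x)), x, tolerance = 1e-8)
  }
})

test_that("estimate_ql_prior moment-matches a scaled F model", {
  pr <- estimate_ql_prior(rep(1.7, 30), df_residual = 8L)
  expect_identical(pr$df_prior, Inf)
  expect_equal(pr$sigma2_trend, 1.7)

  # sigma2 drawn from the generating model with known prior df d0 = 5
  set.seed(23)
  d <- 10L; d0 <- 5; s0 <- 1.3
  sigma2 <- s0 * stats::rf(2000, d, d0)
  pr <- estimate_ql_prior(sigma2, d)
  expect_gt(pr$df_prior, 3.5)
  expect_lt(pr$df_prior, 7)
  expect_equal(pr$sigma2_trend, s0, tolerance = 0.15)

  expect_warning(pr2 <- estimate_ql_prior(rep(c(1, 2), 4), 5L), "fewer than 10")
  expect_identical(pr2$df_prior, Inf)
})

test_that("prior estimation agrees with an independent empirical-Bayes implementation", {
  set.seed(29)
  sigma2 <- 1.4 * stats::rf(1500, 12, 8)
  ours <- estimate_ql_prior(sigma2, 12L)
  ref <- limma::fitFDist(sigma2, df1 = 12)
  expect_equal(ours$df_prior, ref$df2, tolerance = 0.05)
  expect_equal(ours$sigma2_trend, ref$scale, tolerance = 0.05)
})

test_that("shrinkage interpolates between gene and prior and handles infinite prior df", {
  s2 <- c(0.5, 1, 4)
  pr <- list(sigma2_trend = 1, df_prior = 6)
  shr <- shrink_quasi_dispersions(s2, pr, df_residual = 3)
  expect_equal(shr, (6 * 1 + 3 * s2) / 9)
  pr_inf <- list(sigma2_trend = 2, df_prior = Inf)
  expect_equal(shrink_quasi_dispersions(s2, pr_inf, 3), rep(2, 3))
})

test_that("ql_f_test computes the F statistic, p-value and chi-square limit", {
  full <- list(deviance = 3, df_residual = 6L)
  red <- list(deviance = 3, df_residual = 7L)
  ts <- ql_f_test(full, red, sigma2_shrunk = 1.2, df_prior = 4)
  expect_equal(ts$f_statistic, 0)
  expect_equal(ts$pval, 1)

  red9 <- list(deviance = 12, df_residual = 7L)
  ts2 <- ql_f_test(full, red9, sigma2_shrunk = 1.5, df_prior = Inf)
  expect_equal(ts2$f_statistic, 6)
  expect_equal(ts2$pval, pchisq(6, df = 1, lower.tail = FALSE))

  ts3 <- ql_f_test(full, red9, sigma2_shrunk = 1.5, df_prior = 4)
  expect_equal(ts3$pval, pf(6, 1, 10, lower.tail = FALSE))

  bad_red <- list(deviance = 2.9, df_residual = 7L)
  expect_error(ql_f_test(full, bad_red, 1, Inf), "inconsistent")
  tiny_neg <- list(deviance = 3 - 1e-9, df_residual = 7L)
  expect_equal(ql_f_test(full, tiny_neg, 1, Inf)$f_statistic, 0)
  expect_error(ql_f_test(full, list(deviance = 1, df_residual = 6L), 1, Inf),
               "strict subspace")
})

test_that("bh_adjust equals the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
  p[c(3, 50)] <- NA
  expect_identical(is.na(bh_adjust(p)), is.na(p))
})

test_that("contrast_lfc is the scaled dot product with beta", {
  f <- list(beta = c(a = log(4), b = log(2)))
  expect_equal(contrast_lfc(f, c(0, 0)), 0)
  expect_equal(contrast_lfc(f, c(0, 1)), 1)
  expect_equal(contrast_lfc(f, c(1, -2)), (log(4) - 2 * log(2)) / log(2))
  expect_error(contrast_lfc(f, c(1, 2, 3)), "length")
})

test_that("two-group LFC of group means 4 and 8 is 1 at theta = 0", {
  n <- 30
  grp <- rep(0:1, each = n / 2)
  y <- rep(c(4L, 8L), each = n / 2)
  f <- fit_beta(y, cbind(intercept = 1, groupB = grp), theta = 0)
  expect_equal(contrast_lfc(f, c(0, 1)), 1, tolerance = 1e-9)
})

test_that("F statistics are invariant to span-preserving reparameterization", {
  sim <- simulate_counts(15, 40, X = two_group_design(40),
                         beta = cbind(log(6), 0.4), theta = 0.3,
                         sf_log_sd = 0.2, seed = 13)
  fit1 <- gp_fit(sim$counts, sim$X, size_factors = sim$size_factors)
  r1 <- gp_test_de(fit1, reduced = "intercept", contrast = "groupB")

  # same column spans: full {1, group} -> {1, 1 - 2*group}; reduced {1} -> {3}
  X2 <- cbind(one = 1, flip = 1 - 2 * sim$X[, "groupB"])
  fit2 <- gp_fit(sim$counts, X2, size_factors = sim$size_factors)
  r2 <- gp_test_de(fit2, reduced = matrix(3, 40, 1, dimnames = list(NULL, "c")),
                   contrast = "flip")
  expect_equal(r1$f_statistic, r2$f_statistic, tolerance = 1e-8)
  expect_equal(r1$pval, r2$pval, tolerance = 1e-8)
})

test_that("reduced = full gives p = 1 and non-nested designs error", {
  sim <- simulate_counts(8, 20, X = two_group_design(20),
                         beta = cbind(log(5), 0.3), theta = 0.2, seed = 19)
  # 8 genes: the trend and prior legitimately warn about the small panel
  suppressWarnings(fit <- gp_fit(sim$counts, sim$X, size_factors = sim$size_factors))
  expect_error(gp_test_de(fit, reduced = c("intercept", "groupB")),
               "at least one coefficient")
  expect_error(gp_test_de(fit, reduced = matrix(rnorm(20), 20, 1)),
               "not nested")
  # nested test with an honest reduction: p in [0, 1], padj >= p
  r <- suppressWarnings(gp_test_de(fit, reduced = "intercept"))
  expect_true(all(r$pval >= 0 & r$pval <= 1))
  expect_true(all(r$padj >= r$pval - 1e-12))
})
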