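test_that("intercept-only MLE equals the (size-factor weighted) mean count", {
  X <- matrix(1, 3, 1)
  # Poisson branch
  f <- fit_beta(c(1, 2, 3), X, theta = 0)
  expect_equal(unname(f$beta), log(2), tolerance = 1e-10)
  # NB score sum((y - mu) / (mu (1 + theta mu))) vanishes at mu = mean(y)
  f <- fit_beta(c(1, 2, 3), X, theta = 0.7)
  expect_equal(unname(f$beta), log(2), tolerance = 1e-9)
  # offsets: closed form sum(y) / sum(s)
  f <- fit_beta(c(1, 2, 3), X, offsets = log(c(1, 1, 2)), theta = 0)
  expect_equal(unname(f$beta), log(6 / 4), tolerance = 1e-10)
  expect_true(f$converged)
  expect_equal(f$mu, c(1, 1, 2) * 6 / 4, tolerance = 1e-9)
})

test_that("one-hot designs reproduce size-factor-weighted group means exactly", {
  set.seed(21)
  n <- 40
  grp <- rep(c(0, 1), each = n / 2)
  X <- cbind(g0 = 1 - grp, g1 = grp)
  sf <- exp(rnorm(n, 0, 0.3))
  y <- rpois(n, sf * ifelse(grp == 1, 12, 3))
  # Poisson: fitted mu is the size-factor-weighted group mean
  f <- fit_beta(y, X, offsets = log(sf), theta = 0)
  for (g in 0:1) {
    idx <- grp == g
    expect_equal(unname(f$mu[idx]),
                 sf[idx] * sum(y[idx]) / sum(sf[idx]), tolerance = 1e-8)
  }
  expect_equal(f$deviance, sum(gp_unit_deviance(y, f$mu, 0)), tolerance = 1e-10)
  expect_equal(f$df_residual, n - 2L)
  # Gamma-Poisson with equal size factors: fitted mu is the plain group mean
  # (the NB score sum((y - mu)/(mu (1 + theta mu))) vanishes at mu = mean(y))
  f2 <- fit_beta(y, X, theta = 0.2)
  for (g in 0:1) {
    idx <- grp == g
    expect_equal(unname(f2$mu[idx]), rep(mean(y[idx]), sum(idx)),
                 tolerance = 1e-8)
  }
  expect_equal(f2$deviance, sum(gp_unit_deviance(y, f2$mu, 0.2)), tolerance = 1e-10)
})

test_that("initialize_beta is the least-squares solution of the shifted-log transform", {
  X <- matrix(1, 3, 1)
  expect_equal(unname(initialize_beta(c(0, 0, 0), X)), log(0.5))
  expect_equal(unname(initialize_beta(c(3, 3, 3), X)), log(3.5))
  # saturated one-hot design: exact group means of log((y + 0.5) / s)
  grp <- c(0, 0, 1, 1)
  X2 <- cbind(1 - grp, grp)
  y <- c(2, 5, 0, 7)
  s <- c(1, 2, 1, 1)
  b <- initialize_beta(y, X2, offsets = log(s))
  z <- log((y + 0.5) / s)
  expect_equal(unname(b), c(mean(z[1:2]), mean(z[3:4])), tolerance = 1e-12)
})

test_that("all-zero genes short-circuit to a flagged boundary fit", {
  f <- fit_beta(rep(0L, 10), cbind(1, rnorm(10)), theta = 0.4)
  expect_true(f$converged)
  expect_true("all_zero" %in% f$flags)
  expect_equal(f$deviance, 0)
  expect_equal(unname(f$beta), c(-30, 0))
})

test_that("IRLS deviance never ends above the starting deviance and score vanishes", {
  for (seed in 1:10) {
    inst <- random_instance(n = 15, p = 2, theta = 0.4, seed = seed)
    b0 <- initialize_beta(inst$y, inst$X, inst$offsets)
    mu0 <- exp(pmin(pmax(inst$offsets + drop(inst$X %*% b0), -30), 30))
    dev0 <- sum(gp_unit_deviance(inst$y, mu0, 0.4))
    f <- fit_beta(inst$y, inst$X, inst$offsets, theta = 0.4)
    expect_lte(f$deviance, dev0 + 1e-10)
    score <- drop(crossprod(inst$X, (inst$y - f$mu) / (1 + 0.4 * f$mu)))
    expect_lt(max(abs(score)), 1e-6 * (1 + abs(sum(inst$y))))
  }
})

test_that("scaling all size factors shifts only the intercept by -log k", {
  inst <- random_instance(n = 30, p = 3, theta = 0.3, seed = 5)
  f1 <- fit_beta(inst$y, inst$X, inst$offsets, theta = 0.3)
  k <- 4.7
  f2 <- fit_beta(inst$y, inst$X, inst$offsets + log(k), theta = 0.3)
  expect_equal(unname(f2$beta[1]), unname(f1$beta[1]) - log(k), tolerance = 1e-8)
  expect_equal(unname(f2$beta[-1]), unname(f1$beta[-1]), tolerance = 1e-8)
})

test_that("beta matches direct likelihood maximization on small instances", {
  for (seed in 1:12) {
    p <- 1 + seed %% 3
    inst <- random_instance(n = 12 + p, p = p, theta = 0.25, seed = 100 + seed)
    f <- fit_beta(inst$y, inst$X, inst$offsets, theta = 0.25)
    if (!f$converged) next
    oracle <- oracle_direct_beta(inst$y, inst$X, inst$offsets, 0.25,
                                 start = unname(f$beta) + 0.3)
    expect_equal(unname(f$beta), unname(oracle$beta), tolerance = 1e-4)
  }
})

test_that("design validation catches rank deficiency and saturated designs", {
  X <- cbind(a = rep(1, 5), b = 1:5, c = 2 * (1:5))
  expect_error(check_design(X), "collinear column\\(s\\): c")
  expect_error(check_design(diag(5)), "residual degrees of freedom")
  expect_error(fit_beta(c(1, NA, 2), matrix(1, 3, 1)), "finite")
})

test_that("fit_all_genes is invariant to chunk size and matches single fits", {
  sim <- simulate_counts(20, 30, X = two_group_design(30),
                         beta = cbind(log(4), 0.5), theta = 0.3,
                         sf_log_sd = 0.2, seed = 77)
  X <- sim$X
  f1g <- fit_all_genes(sim$counts[1, , drop = FALSE], X, sim$size_factors,
                       theta_mode = "zero")
  direct <- fit_beta(sim$counts[1, ], X, log(sim$size_factors), theta = 0)
  expect_equal(f1g[[1]]$beta, direct$beta)

  ref <- fit_all_genes(sim$counts, X, sim$size_factors, theta_mode = "estimate")
  for (cs in c(1, 7, 20)) {
    alt <- fit_all_genes(sim$counts, X, sim$size_factors,
                         theta_mode = "estimate", chunk_size = cs)
    expect_equal(vapply(alt, `[[`, numeric(2), "beta"),
                 vapply(ref, `[[`, numeric(2), "beta"), tolerance = 1e-10)
    expect_equal(vapply(alt, `[[`, 1.0, "theta_est"),
                 vapply(ref, `[[`, 1.0, "theta_est"), tolerance = 1e-10)
  }
  expect_error(fit_all_genes(sim$counts, two_group_design(10), sim$size_factors),
               "cells")
})

test_that("fixed-theta fits recover simulated intercepts within 3 SE", {
  G <- 100; n <- 150
  b0 <- rnorm(G, log(6), 0.4)
  sim <- simulate_counts(G, n, beta = matrix(b0), theta = 0.5,
                         sf_log_sd = 0.2, seed = 303)
  fits <- fit_all_genes(sim$counts, matrix(1, n, 1), sim$size_factors,
                        theta_mode = "fixed", theta_values = rep(0.5, G))
  bhat <- vapply(fits, function(f) unname(f$beta[1]), 1.0)
  # observed-information SE of the intercept: 1/sqrt(sum(mu/(1+theta mu)))
  se <- vapply(fits, function(f) 1 / sqrt(sum(f$mu / (1 + 0.5 * f$mu))), 1.0)
  expect_lt(mean(abs(bhat - b0)), 3 * mean(se))
})
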