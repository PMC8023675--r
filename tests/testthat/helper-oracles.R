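# Independent oracles, kept deliberately separate from the package's code
# paths: explicit formulas, grid searches and derivative-free optimization.

# negative binomial / Poisson log-pmf from the explicit lgamma formula
oracle_logpmf <- function(y, mu, theta) {
  if (theta == 0) {
    ifelse(y == 0 & mu == 0, 0, y * log(mu) - mu - lgamma(y + 1))
  } else {
    lgamma(y + 1 / theta) - lgamma(1 / theta) - lgamma(y + 1) +
      y * log(theta * mu / (1 + theta * mu)) - (1 / theta) * log(1 + theta * mu)
  }
}

oracle_loglik <- function(y, mu, theta) sum(oracle_logpmf(y, mu, theta))

# unit deviance as twice the log-likelihood gap to the saturated model with
# the saturated mean clamped at max(y, eps)
oracle_unit_deviance <- function(y, mu, theta, eps = 1e-10) {
  sat <- pmax(y, eps)
  2 * (oracle_logpmf(y, sat, theta) - oracle_logpmf(y, mu, theta))
}

# dense grid search for the ML overdispersion (optionally Cox-Reid adjusted)
oracle_grid_theta <- function(y, mu, X = NULL, cox_reid = FALSE,
                              n_grid = 10000L, lo = 1e-6, hi = 1e4) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  obj <- vapply(grid, function(th) {
    ll <- oracle_loglik(y, mu, th)
    if (cox_reid) {
      w <- mu / (1 + th * mu)
      ll <- ll - 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
    }
    as.numeric(ll)
  }, 1.0)
  grid[which.max(obj)]
}

# derivative-free direct maximization of the gene log-likelihood over beta
oracle_direct_beta <- function(y, X, offsets, theta, start) {
  nll <- function(b) {
    mu <- exp(pmin(pmax(offsets + drop(X %*% b), -30), 30))
    -oracle_loglik(y, mu, theta)
  }
  if (length(start) == 1L) {
    opt <- stats::optimize(function(b) nll(b), interval = start + c(-10, 10))
    list(beta = opt$minimum, loglik = -opt$objective)
  } else {
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    list(beta = opt$par, loglik = -opt$value)
  }
}

# joint direct search over (beta..., log theta)
oracle_direct_joint <- function(y, X, offsets, start_beta, start_theta) {
  nll <- function(par) {
    b <- par[-length(par)]; th <- exp(par[length(par)])
    mu <- exp(pmin(pmax(offsets + drop(X %*% b), -30), 30))
    -oracle_loglik(y, mu, th)
  }
  opt <- stats::optim(c(start_beta, log(start_theta + 0.05)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-14))
  list(beta = opt$par[-length(opt$par)], theta = exp(opt$par[length(opt$par)]),
       loglik = -opt$value)
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- rep(NA_real_, m)
  running <- Inf
  rank_desc <- m:1
  for (k in seq_along(ord)) {
    i <- ord[k]
    running <- min(running, p[i] * m / rank_desc[k])
    adj[i] <- min(running, 1)
  }
  adj
}

# small random GP test instance
random_instance <- function(n = 8, p = 1, theta = 0.3, seed = 1) {
  set.seed(seed)
  X <- if (p == 1) matrix(1, n, 1) else cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- paste0("b", seq_len(p))
  beta <- c(log(runif(1, 2, 10)), rnorm(p - 1, 0, 0.5))
  sf <- exp(rnorm(n, 0, 0.2))
  mu <- sf * exp(drop(X %*% beta))
  y <- if (theta == 0) rpois(n, mu) else
    rpois(n, rgamma(n, shape = 1 / theta, scale = theta * mu))
  list(y = y, X = X, sf = sf, offsets = log(sf), beta = beta, theta = theta)
}
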