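# Overdispersion estimation. The gene log-likelihood is evaluated over a
# bundled representation of the (count, fitted-mean) pairs: most entries of a
# single-cell count matrix take a small set of integer values, and under
# group-like designs the fitted means take one value per group, so the
# per-gene likelihood collapses to a short weighted sum. Bundling only merges
# mathematically identical means (relative tolerance 1e-10), so it is exact,
# not an approximation.

THETA_LOWER <- 1e-8
THETA_UPPER <- 1e6

#' Bundle repeated (count, mean) pairs of one gene
#'
#' Groups the observations of one gene by identical count value and
#' (numerically identical) fitted mean, recording each distinct pair once with
#' its multiplicity. Falls back to the dense representation (one pair per
#' cell) when fewer than half of the observations are repeats, so the
#' worst-case cost of downstream likelihood evaluation never exceeds the naive
#' implementation.
#'
#' @param y non-negative integer counts.
#' @param mu fitted means, same length.
#' @param mu_tol relative tolerance within which two means are considered the
#'   same value. The default `1e-10` merges only means that are equal up to
#'   floating-point noise (e.g. within design groups).
#' @return a `bundled_gene` list with `y` (count values), `mu` (mean values),
#'   `m` (multiplicities summing to the number of cells), `n` and `dense`
#'   (fallback indicator).
#' @export
bundle_counts <- function(y, mu, mu_tol = 1e-10) {
  n <- length(y)
  if (length(mu) != n) stop("`y` and `mu` must have the same length")
  if (n == 0L) {
    return(structure(list(y = numeric(0), mu = numeric(0), m = integer(0),
                          n = 0L, dense = FALSE), class = "bundled_gene"))
  }
  ord <- order(y, mu)
  ys <- y[ord]; mus <- mu[ord]
  # new group whenever the count changes or the mean moves by more than mu_tol
  # relative to the previous value
  new_grp <- c(TRUE, ys[-1] != ys[-n] |
                 abs(mus[-1] - mus[-n]) > mu_tol * pmax(abs(mus[-n]), 1e-300))
  grp <- cumsum(new_grp)
  k <- grp[n]
  if (k > 0.5 * n) {
    return(structure(list(y = as.numeric(y), mu = as.numeric(mu),
                          m = rep(1L, n), n = n, dense = TRUE),
                     class = "bundled_gene"))
  }
  first <- which(new_grp)
  structure(list(y = as.numeric(ys[first]), mu = as.numeric(mus[first]),
                 m = as.integer(tabulate(grp, k)), n = n, dense = FALSE),
            class = "bundled_gene")
}

bundled_loglik <- function(bundle, theta) {
  if (bundle$n == 0L) return(0)
  sum(bundle$m * gp_logpmf(bundle$y, bundle$mu, theta))
}

#' Method-of-moments overdispersion start value
#'
#' `theta0 = max(0, sum((y - mu)^2 - mu) / sum(mu^2))`, the moment estimator
#' from `Var(Y) = mu + theta mu^2`. Used to initialize the likelihood search.
#'
#' @param y counts.
#' @param mu fitted means.
#' @return single non-negative finite start value.
#' @export
moments_start <- function(y, mu) {
  if (length(y) < 2L) stop("need at least 2 observations")
  max(0, sum((y - mu)^2 - mu) / sum(mu^2))
}

#' Maximum-likelihood overdispersion for one gene
#'
#' Maximizes `f(theta) = sum_i m_i * gp_logpmf(y_i, mu_i, theta)` (minus the
#' Cox-Reid adjustment `0.5 * logdet(X' W(theta) X)` when `cox_reid = TRUE`,
#' with `W = diag(mu / (1 + theta mu))` over all cells) over
#' `log theta in [log 1e-8, log 1e6]`. The search starts from the
#' method-of-moments estimate, expands a bracket around it, then refines with
#' golden-section/parabolic interpolation ([stats::optimize()]). Solutions at
#' the lower boundary are returned as exactly 0 with the `boundary` attribute
#' set; the attained objective is never below the objective at the moments
#' start.
#'
#' @param bundle a `bundled_gene` from [bundle_counts()], or `NULL` to bundle
#'   `y`/`mu` internally.
#' @param X design matrix (needed for the Cox-Reid term).
#' @param cox_reid apply the Cox-Reid bias adjustment (default `TRUE`).
#' @param y,mu dense counts and fitted means; `mu` is required when
#'   `cox_reid = TRUE` (the adjustment is evaluated cell-wise), `y` only when
#'   `bundle` is not supplied.
#' @return single non-negative theta estimate with attributes `boundary`
#'   (logical) and `objective` (attained adjusted log-likelihood).
#' @export
estimate_theta <- function(bundle = NULL, X = NULL, cox_reid = TRUE,
                           y = NULL, mu = NULL) {
  if (is.null(bundle)) {
    if (is.null(y) || is.null(mu)) stop("supply `bundle` or both `y` and `mu`")
    bundle <- bundle_counts(y, mu)
  }
  if (cox_reid) {
    if (is.null(X) || is.null(mu)) {
      stop("`X` and dense `mu` are required for the Cox-Reid adjustment")
    }
    X <- as.matrix(X)
  }

  objective <- function(log_theta) {
    theta <- exp(log_theta)
    ll <- bundled_loglik(bundle, theta)
    if (cox_reid) {
      w <- mu / (1 + theta * mu)
      R <- qr.R(qr(X * sqrt(w)))
      ll <- ll - sum(log(abs(diag(R))))  # 0.5 * logdet(X' W X)
    }
    ll
  }

  if (is.null(y)) y <- rep(bundle$y, bundle$m)
  mu_dense <- if (is.null(mu)) rep(bundle$mu, bundle$m) else mu
  theta0 <- max(moments_start(y, mu_dense), 10 * THETA_LOWER)
  theta0 <- min(theta0, THETA_UPPER / 10)
  lt0 <- log(theta0)
  f0 <- objective(lt0)

  # expand a bracket around the start until the maximum is interior or the
  # global bounds are reached
  lo <- max(lt0 - log(8), log(THETA_LOWER))
  hi <- min(lt0 + log(8), log(THETA_UPPER))
  f_lo <- objective(lo); f_hi <- objective(hi)
  best <- max(f0, f_lo, f_hi)
  while (f_lo >= best - 1e-12 && lo > log(THETA_LOWER) + 1e-9) {
    lo <- max(lo - log(8), log(THETA_LOWER))
    f_lo <- objective(lo); best <- max(best, f_lo)
  }
  while (f_hi >= best - 1e-12 && hi < log(THETA_UPPER) - 1e-9) {
    hi <- min(hi + log(8), log(THETA_UPPER))
    f_hi <- objective(hi); best <- max(best, f_hi)
  }

  opt <- stats::optimize(objective, lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(lt0, f0), c(lo, f_lo), c(hi, f_hi))
  pick <- cand[which.max(cand[, 2]), ]
  log_theta_hat <- pick[1]; obj_hat <- pick[2]

  # polish with bisection on the analytic score d(objective)/d(log theta):
  # a value-based search cannot localize a flat maximum beyond ~sqrt(eps),
  # and the score is exactly invariant to reparameterization of the design
  score_lt <- function(log_theta) {
    theta <- exp(log_theta)
    k <- 1 / theta
    dldk <- sum(bundle$m * (digamma(bundle$y + k) - digamma(k) +
                              log(k / (k + bundle$mu)) +
                              (bundle$mu - bundle$y) / (k + bundle$mu)))
    g <- -k^2 * dldk
    if (cox_reid) {
      w <- mu / (1 + theta * mu)
      M <- crossprod(X * sqrt(w))
      g <- g + 0.5 * sum(diag(solve(M, crossprod(X * w))))
    }
    theta * g
  }
  if (log_theta_hat > log(THETA_LOWER) + 1e-6 &&
      log_theta_hat < log(THETA_UPPER) - 1e-6) {
    a <- max(log_theta_hat - 0.05, log(THETA_LOWER))
    b <- min(log_theta_hat + 0.05, log(THETA_UPPER))
    ga <- score_lt(a); gb <- score_lt(b)
    if (is.finite(ga) && is.finite(gb) && ga > 0 && gb < 0) {
      for (i in 1:60) {
        mid <- (a + b) / 2
        gm <- score_lt(mid)
        if (!is.finite(gm)) break
        if (gm > 0) a <- mid else b <- mid
      }
      cand_lt <- (a + b) / 2
      cand_obj <- objective(cand_lt)
      if (cand_obj >= obj_hat - 1e-9) {
        log_theta_hat <- cand_lt
        obj_hat <- max(cand_obj, obj_hat)
      }
    }
  }

  boundary <- FALSE
  # lower-boundary solution: the Poisson limit fits at least as well
  f_pois <- bundled_loglik(bundle, 0) - if (cox_reid) {
    w <- mu_dense
    sum(log(abs(diag(qr.R(qr(X * sqrt(w)))))))
  } else 0
  theta_hat <- exp(log_theta_hat)
  if (log_theta_hat <= log(THETA_LOWER) + 1e-6 || f_pois >= obj_hat - 1e-10) {
    theta_hat <- 0
    obj_hat <- max(obj_hat, f_pois)
    boundary <- TRUE
  } else if (log_theta_hat >= log(THETA_UPPER) - 1e-6) {
    boundary <- TRUE
  }
  structure(theta_hat, boundary = boundary, objective = obj_hat)
}

#' Joint per-gene fit of coefficients and overdispersion
#'
#' Alternates [fit_beta()] at fixed theta with [estimate_theta()] at fixed
#' fitted means, starting from the method-of-moments theta after a Poisson
#' pre-fit, until the change in `log(theta + 1e-8)` falls below `1e-4` and the
#' coefficient fit has converged (at most 10 outer rounds). Non-convergence is
#' flagged on the returned fit, never raised.
#'
#' @param y non-negative integer counts per cell.
#' @param X design matrix.
#' @param size_factors positive per-cell size factors.
#' @param cox_reid use the Cox-Reid adjusted likelihood for theta.
#' @param theta_mode `"estimate"` or `"zero"` (Poisson fit, skipping theta
#'   estimation entirely).
#' @return `gene_fit` with elements `theta_est` (the estimate used and
#'   returned in `theta_used`) and `outer_rounds` added.
#' @export
fit_gene <- function(y, X, size_factors = NULL, cox_reid = TRUE,
                     theta_mode = c("estimate", "zero")) {
  theta_mode <- match.arg(theta_mode)
  X <- as.matrix(X)
  if (is.null(size_factors)) size_factors <- rep(1, length(y))
  offsets <- log(size_factors)

  fit <- fit_beta(y, X, offsets, theta = 0)
  if (theta_mode == "zero" || "all_zero" %in% fit$flags) {
    fit$theta_est <- 0
    fit$outer_rounds <- 0L
    return(fit)
  }

  theta <- moments_start(y, fit$mu)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    fit <- fit_beta(y, X, offsets, theta = theta, beta_init = fit$beta)
    th_new <- as.numeric(estimate_theta(bundle_counts(y, fit$mu), X = X,
                                        cox_reid = cox_reid, y = y, mu = fit$mu))
    delta <- abs(log(th_new + 1e-8) - log(theta + 1e-8))
    theta <- th_new
    if ((delta < 1e-4 && fit$converged) || rounds >= 10L) break
  }
  if (abs(fit$theta_used - theta) > 0) {
    fit <- fit_beta(y, X, offsets, theta = theta, beta_init = fit$beta)
  }
  fit$theta_est <- theta
  fit$outer_rounds <- rounds
  fit
}

#' Dispersion-mean trend by running median
#'
#' Smooths gene-wise overdispersion estimates against mean expression: genes
#' are sorted by log mean expression, a running median of theta over a
#' centered window of `max(11, 5%)` genes is taken, and the window medians are
#' linearly interpolated in log-mean space back onto every gene. The trend is
#' floored at `1e-8` so it is strictly positive. With fewer than 10 genes of
#' positive mean expression the trend is the constant median theta, with a
#' warning.
#'
#' @param theta_gene per-gene overdispersion estimates.
#' @param mean_expression per-gene mean (size-factor normalized) expression.
#' @return per-gene trended theta, same order as the input.
#' @export
fit_trend <- function(theta_gene, mean_expression) {
  stopifnot(length(theta_gene) == length(mean_expression))
  G <- length(theta_gene)
  usable <- is.finite(theta_gene) & is.finite(mean_expression) & mean_expression > 0
  if (sum(usable) < 10L) {
    warning("fewer than 10 genes with positive mean expression; using a constant trend")
    const <- stats::median(theta_gene[is.finite(theta_gene)])
    return(rep(max(const, 1e-8), G))
  }
  lx <- log(mean_expression[usable])
  th <- theta_gene[usable]
  ord <- order(lx)
  k <- max(11L, ceiling(0.05 * sum(usable)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, sum(usable))
  if (k %% 2L == 0L) k <- k - 1L
  sm <- stats::runmed(th[ord], k, endrule = "median")
  # collapse duplicate x positions, then interpolate in log-mean space
  fx <- lx[ord]
  ag <- tapply(sm, fx, stats::median)
  xs <- sort(unique(fx))
  trend_at <- if (length(xs) < 2L) {
    function(x) rep(as.numeric(ag)[1], length(x))
  } else {
    function(x) stats::approx(xs, as.numeric(ag), xout = x, rule = 2)$y
  }
  out <- numeric(G)
  out[usable] <- trend_at(lx)
  # genes with zero mean expression take the trend value at the lowest mean
  out[!usable] <- trend_at(min(lx))
  pmax(out, 1e-8)
}
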