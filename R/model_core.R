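#' Gamma-Poisson log probability mass
#'
#' Log-probability of observing count `y` under a Gamma-Poisson (negative
#' binomial) distribution with mean `mu` and overdispersion `theta`, in the
#' mean/overdispersion parameterization where `Var(Y) = mu + theta * mu^2`.
#' `theta = 0` is the Poisson limit and is evaluated by a dedicated Poisson
#' branch, not by taking a numerical limit of the negative binomial formula.
#'
#' @param y vector of non-negative integer counts.
#' @param mu vector of expected counts; must be positive except that `mu = 0`
#'   is allowed where `y = 0` (a point mass at zero, contributing
#'   log-probability 0).
#' @param theta single non-negative overdispersion. `theta` is the reciprocal
#'   of the classical negative binomial `size`.
#' @return vector of log-probabilities, finite for all valid inputs.
#' @examples
#' gp_logpmf(0, mu = 1, theta = 0)   # log exp(-1) = -1
#' gp_logpmf(0, mu = 1, theta = 1)   # -log(2)
#' @export
gp_logpmf <- function(y, mu, theta) {
  check_counts(y)
  check_mu_theta(y, mu, theta)
  if (theta == 0) {
    stats::dpois(y, lambda = mu, log = TRUE)
  } else {
    # dnbinom with size = 1/theta, mu = mu is exactly
    # lgamma(y+1/theta) - lgamma(1/theta) - lgamma(y+1)
    #   + y*log(theta*mu/(1+theta*mu)) - (1/theta)*log(1+theta*mu)
    stats::dnbinom(y, size = 1 / theta, mu = mu, log = TRUE)
  }
}

#' Gamma-Poisson unit deviance
#'
#' Twice the log-likelihood gap between the saturated model (mean equal to the
#' observation) and the fitted mean, `2 * (ll(y; y, theta) - ll(y; mu, theta))`,
#' evaluated in its analytic limit form so the `0 * log(0)` terms at `y = 0`
#' vanish exactly. Reduces to the Poisson unit deviance
#' `2 * (y * log(y / mu) - (y - mu))` when `theta = 0`.
#'
#' @inheritParams gp_logpmf
#' @return vector of non-negative unit deviances.
#' @export
gp_unit_deviance <- function(y, mu, theta) {
  check_counts(y)
  check_mu_theta(y, mu, theta)
  n <- max(length(y), length(mu))
  y <- rep_len(as.numeric(y), n)
  mu <- rep_len(as.numeric(mu), n)
  pos <- y > 0
  dev <- numeric(n)
  if (theta == 0) {
    dev[pos] <- 2 * (y[pos] * log(y[pos] / mu[pos]) - (y[pos] - mu[pos]))
    dev[!pos] <- 2 * mu[!pos]
  } else {
    dev[pos] <- 2 * (y[pos] * log(y[pos] / mu[pos]) -
      (y[pos] + 1 / theta) * log1p(theta * y[pos]) +
      (y[pos] + 1 / theta) * log1p(theta * mu[pos]))
    dev[!pos] <- 2 / theta * log1p(theta * mu[!pos])
  }
  # guard tiny negative round-off at the saturated point
  pmax(dev, 0)
}

#' Gene-level Gamma-Poisson log-likelihood
#'
#' Sum of [gp_logpmf()] over the observations of one gene. An empty gene has
#' log-likelihood 0.
#'
#' @param counts non-negative integer counts across cells.
#' @param mus fitted means, same length as `counts`.
#' @param theta single non-negative overdispersion.
#' @return single numeric log-likelihood.
#' @export
gene_loglik <- function(counts, mus, theta) {
  if (length(counts) != length(mus)) {
    stop("`counts` and `mus` must have the same length (", length(counts),
         " vs ", length(mus), ")")
  }
  if (length(counts) == 0L) return(0)
  sum(gp_logpmf(counts, mus, theta))
}

check_counts <- function(y) {
  if (any(!is.finite(y))) stop("counts must be finite")
  if (any(y < 0)) stop("counts must be non-negative")
  if (any(y != floor(y))) stop("counts must be integers")
  invisible(y)
}

check_mu_theta <- function(y, mu, theta) {
  if (length(theta) != 1L || !is.finite(theta) || theta < 0) {
    stop("`theta` must be a single non-negative number")
  }
  if (any(!is.finite(mu)) || any(mu < 0)) stop("`mu` must be non-negative and finite")
  if (any(mu == 0 & rep_len(y, max(length(y), length(mu))) > 0)) {
    stop("`mu` = 0 is only allowed where y = 0")
  }
  invisible(mu)
}
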