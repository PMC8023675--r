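# Quasi-likelihood F-test with empirical-Bayes shrinkage of the gene-wise
# quasi-dispersions (the construction of Lund et al.'s QL framework): both the
# full and the reduced model are fitted at the trended overdispersion, the
# per-gene deviance/df captures residual gene-level variability as a
# quasi-dispersion, and those quasi-dispersions are squeezed toward a common
# location with a prior df estimated by moment matching on the log scale.

#' Quasi-dispersion of a fitted gene
#'
#' `sigma^2 = deviance / df_residual`, floored at `1e-8`, from a full-model
#' fit computed at the trended overdispersion.
#'
#' @param fit_full `gene_fit` of the full model.
#' @return positive quasi-dispersion.
#' @export
quasi_dispersion <- function(fit_full) {
  if (fit_full$df_residual < 1L) {
    stop("gene has no residual degrees of freedom; cannot form a quasi-dispersion")
  }
  max(fit_full$deviance / fit_full$df_residual, 1e-8)
}

#' Empirical-Bayes prior for quasi-dispersions
#'
#' Moment-matches the distribution of `log sigma^2` to that of the log of a
#' scaled F(df_residual, df_prior) variable. If gene-wise quasi-dispersions
#' follow `sigma0^2 * F(d, d0)`, then
#' `Var(log sigma^2) = trigamma(d/2) + trigamma(d0/2)`, so `d0` is obtained by
#' inverting the trigamma function on the excess of the observed variance over
#' `trigamma(d/2)`. Observed variance at or below that theoretical minimum
#' means the quasi-dispersions are exchangeable with no extra spread and the
#' prior df is infinite. The prior location `sigma0^2` is solved from the mean
#' of `log sigma^2` using the corresponding digamma identity.
#'
#' @param sigma2_gene per-gene quasi-dispersions (>= 10 genes for a finite
#'   prior; fewer yields `df_prior = Inf` with a warning).
#' @param df_residual residual degrees of freedom of the full fits (single
#'   integer; genes with differing df should be grouped beforehand).
#' @return list with `sigma2_trend` (prior location) and `df_prior`
#'   (positive, possibly `Inf`).
#' @export
estimate_ql_prior <- function(sigma2_gene, df_residual) {
  sigma2_gene <- sigma2_gene[is.finite(sigma2_gene) & sigma2_gene > 0]
  d <- df_residual
  if (length(sigma2_gene) < 10L) {
    warning("fewer than 10 genes; using an infinite prior df")
    return(list(sigma2_trend = stats::median(sigma2_gene), df_prior = Inf))
  }
  z <- log(sigma2_gene)
  if (stats::var(z) < 1e-12) {
    # degenerate: no spread at all, so no sampling-noise correction applies
    return(list(sigma2_trend = exp(mean(z)), df_prior = Inf))
  }
  excess <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(sigma2_trend = s02, df_prior = d0)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on `1/trigamma`,
#' which is nearly linear; converges in a handful of steps for all practical
#' `y`.
#'
#' @param y positive value(s).
#' @return x with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Shrink gene-wise quasi-dispersions toward the prior
#'
#' `sigma2_shrunk = (d0 * sigma2_trend + d * sigma2_gene) / (d0 + d)`, the
#' posterior mean under the scaled-F model; equals `sigma2_trend` when the
#' prior df is infinite.
#'
#' @param sigma2_gene per-gene quasi-dispersions.
#' @param prior list from [estimate_ql_prior()].
#' @param df_residual residual df of the fits.
#' @return per-gene shrunken quasi-dispersions.
#' @export
shrink_quasi_dispersions <- function(sigma2_gene, prior, df_residual) {
  if (is.infinite(prior$df_prior)) {
    rep(prior$sigma2_trend, length(sigma2_gene))
  } else {
    (prior$df_prior * prior$sigma2_trend + df_residual * sigma2_gene) /
      (prior$df_prior + df_residual)
  }
}

#' Quasi-likelihood F-test for one gene
#'
#' `F = [(deviance_reduced - deviance_full) / df1] / sigma2_shrunk`, floored
#' at 0, referred to `F(df1, df_prior + df_residual)`; an infinite prior df
#' yields the `chi^2_df1 / df1` limit. Both fits must use the same trended
#' overdispersion and size factors. Deviance differences below `-1e-8` signal
#' a fitting bug and raise; smaller negatives are clipped to 0.
#'
#' @param fit_full,fit_reduced `gene_fit` objects for nested designs.
#' @param sigma2_shrunk shrunken quasi-dispersion for this gene.
#' @param df_prior prior degrees of freedom (possibly `Inf`).
#' @return list with `f_statistic`, `df1`, `df2`, `pval`.
#' @export
ql_f_test <- function(fit_full, fit_reduced, sigma2_shrunk, df_prior) {
  df1 <- fit_reduced$df_residual - fit_full$df_residual
  if (df1 < 1L) stop("reduced design must be a strict subspace of the full design")
  ddev <- fit_reduced$deviance - fit_full$deviance
  if (ddev < -1e-8) {
    stop("reduced-model deviance below full-model deviance (", ddev,
         "); fits are inconsistent")
  }
  f <- max(ddev, 0) / df1 / sigma2_shrunk
  df2 <- df_prior + fit_full$df_residual
  pval <- if (is.infinite(df2)) {
    stats::pchisq(df1 * f, df = df1, lower.tail = FALSE)
  } else {
    stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(f_statistic = f, df1 = df1, df2 = df2, pval = pval)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' missing values are propagated.
#'
#' @param p p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold change of a contrast
#'
#' `(contrast' beta) / log(2)` for a fitted gene.
#'
#' @param fit_full `gene_fit` with p coefficients.
#' @param contrast numeric vector of length p.
#' @return log2 fold change.
#' @export
contrast_lfc <- function(fit_full, contrast) {
  if (length(contrast) != length(fit_full$beta)) {
    stop("contrast has length ", length(contrast), " but the fit has ",
         length(fit_full$beta), " coefficients")
  }
  sum(contrast * fit_full$beta) / log(2)
}
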