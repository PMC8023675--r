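# Per-gene Gamma-Poisson GLM fitting: log mu = X beta + offset, beta estimated
# by deviance-minimizing iteratively reweighted least squares (Fisher scoring)
# at a fixed overdispersion theta. theta = 0 is the Poisson fast path.

ETA_CLAMP <- 30          # |linear predictor| bound inside iterations
BETA_DIVERGED <- 50      # ||beta||_inf beyond which a fit is flagged diverged
MAX_HALVINGS <- 20L

#' Validate and annotate a design matrix
#'
#' Checks that `X` is numeric, full column rank and leaves at least one
#' residual degree of freedom. Rank deficiency is an error that names the
#' collinear columns.
#'
#' @param X numeric design matrix (cells x p) with column names.
#' @return `X` with any missing column names filled in.
#' @export
check_design <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("beta", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (ncol(X) >= nrow(X)) {
    stop("design has no residual degrees of freedom (p = ", ncol(X),
         ", cells = ", nrow(X), ")")
  }
  X
}

#' Initial coefficient values for the IRLS fit
#'
#' Ordinary least squares of `log((y + 0.5) / s)` on the design, where
#' `s = exp(offsets)`. The +0.5 keeps all-zero genes finite.
#'
#' @param y non-negative integer counts per cell.
#' @param X design matrix (cells x p).
#' @param offsets per-cell log size factors (recycled if scalar).
#' @return numeric coefficient vector of length p.
#' @export
initialize_beta <- function(y, X, offsets = 0) {
  offsets <- rep_len(offsets, length(y))
  z <- log(y + 0.5) - offsets
  qr.coef(qr(X), z)
}

#' Fit per-gene GLM coefficients at fixed overdispersion
#'
#' Minimizes the Gamma-Poisson deviance of `log mu = X beta + offset` by
#' iteratively reweighted least squares with working weights
#' `w = mu / (1 + theta * mu)` and working response
#' `z = eta + (y - mu) / mu`. Each step solves the weighted least-squares
#' normal equations through a rank-revealing QR decomposition; step-halving
#' (up to 20 halvings) is applied whenever a step would increase the deviance,
#' so the deviance is non-increasing across accepted iterations. The linear
#' predictor is clamped to `[-30, 30]`; a fit ending on the clamp boundary or
#' with `||beta||_inf > 50` is flagged non-converged rather than raising.
#'
#' Convergence requires a relative deviance change below `tol` and the score
#' `X' [(y - mu) / (1 + theta * mu)]` to vanish within
#' `1e-6 * (1 + |sum(y)|)` componentwise.
#'
#' All-zero genes short-circuit to the boundary fit `beta = (-30, 0, ..., 0)`
#' with zero deviance, flagged `all_zero`.
#'
#' @param y non-negative integer counts per cell.
#' @param X design matrix (cells x p), full rank.
#' @param offsets per-cell log size factors.
#' @param theta fixed non-negative overdispersion for this fit.
#' @param beta_init optional starting coefficients; defaults to
#'   [initialize_beta()].
#' @param max_iter,tol iteration cap and relative-deviance convergence
#'   tolerance.
#' @return a `gene_fit` list: `beta`, fitted `mu` (`s_c * exp((X beta)_c)`),
#'   `theta_used`, `deviance`, `df_residual`, `iterations`, `converged`, and a
#'   character vector `flags`.
#' @export
fit_beta <- function(y, X, offsets = 0, theta = 0, beta_init = NULL,
                     max_iter = 100L, tol = 1e-11) {
  X <- as.matrix(X)
  if (any(!is.finite(y))) stop("counts must be finite")
  check_counts(y)
  n <- length(y)
  if (nrow(X) != n) stop("length(y) must equal nrow(X)")
  p <- ncol(X)
  offsets <- rep_len(as.numeric(offsets), n)

  if (all(y == 0)) {
    beta <- c(-ETA_CLAMP, rep(0, p - 1))
    names(beta) <- colnames(X)
    mu <- exp(pmin(pmax(offsets + drop(X %*% beta), -ETA_CLAMP), ETA_CLAMP))
    return(new_gene_fit(beta, mu, theta, deviance = 0, df_residual = n - p,
                        iterations = 0L, converged = TRUE, flags = "all_zero"))
  }

  beta <- if (is.null(beta_init)) initialize_beta(y, X, offsets) else beta_init
  eta <- clamp_eta(offsets + drop(X %*% beta))
  mu <- exp(eta)
  dev <- sum(gp_unit_deviance(y, mu, theta))
  flags <- character()
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + theta * mu)
    z <- (eta - offsets) + (y - mu) / mu
    ok <- is.finite(w) & w > 0 & is.finite(z)
    if (!all(ok)) { flags <- union(flags, "degenerate_weights"); break }
    beta_prop <- stats::lm.wfit(X, z, w)$coefficients
    if (anyNA(beta_prop)) { flags <- union(flags, "singular_step"); break }

    step <- 1
    halvings <- 0L
    repeat {
      beta_new <- beta + step * (beta_prop - beta)
      eta_new <- clamp_eta(offsets + drop(X %*% beta_new))
      mu_new <- exp(eta_new)
      dev_new <- sum(gp_unit_deviance(y, mu_new, theta))
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      halvings <- halvings + 1L
      if (halvings > MAX_HALVINGS) break
      step <- step / 2
    }
    if (halvings > MAX_HALVINGS) { flags <- union(flags, "step_halving_failed"); break }

    delta <- abs(dev - dev_new) / (abs(dev) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; dev <- dev_new
    # stationarity: the score must vanish, not just the deviance plateau
    score <- drop(crossprod(X, (y - mu) / (1 + theta * mu)))
    score_ok <- max(abs(score)) <= 1e-6 * (1 + abs(sum(y)))
    if (delta < tol && score_ok) { converged <- TRUE; break }
  }

  score <- drop(crossprod(X, (y - mu) / (1 + theta * mu)))
  score_ok <- max(abs(score)) <= 1e-6 * (1 + abs(sum(y)))
  if (max(abs(beta)) > BETA_DIVERGED) {
    flags <- union(flags, "diverged"); converged <- FALSE
  }
  on_clamp <- any(abs(offsets + drop(X %*% beta)) >= ETA_CLAMP - 1e-8)
  if (on_clamp) { flags <- union(flags, "eta_clamped"); converged <- FALSE }
  if (!score_ok && !on_clamp) converged <- FALSE

  names(beta) <- colnames(X)
  new_gene_fit(beta, mu, theta, dev, n - ncol(X), iter, converged, flags)
}

clamp_eta <- function(eta) pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)

new_gene_fit <- function(beta, mu, theta_used, deviance, df_residual,
                         iterations, converged, flags = character()) {
  structure(list(beta = beta, mu = mu, theta_used = theta_used,
                 deviance = deviance, df_residual = as.integer(df_residual),
                 iterations = as.integer(iterations), converged = converged,
                 flags = flags),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit> beta:", paste(signif(x$beta, 4), collapse = " "),
      " theta:", signif(x$theta_used, 4),
      " deviance:", signif(x$deviance, 6),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Fit every gene of a count matrix, streaming over gene chunks
#'
#' Applies [fit_gene()] (or the fixed-theta [fit_beta()]) independently to each
#' gene, iterating over contiguous gene chunks so only `chunk_size` genes are
#' resident at a time. Results are identical for any chunk size and for
#' in-memory or on-disk backends.
#'
#' @param counts gene x cell matrix, or a `matrix_handle` from
#'   [read_matrix()].
#' @param X design matrix (cells x p).
#' @param size_factors positive per-cell size factors (default all 1).
#' @param theta_mode `"estimate"` (alternating beta/theta maximum likelihood),
#'   `"zero"` (Poisson fast path) or `"fixed"` (use `theta_values`).
#' @param theta_values per-gene overdispersions for `theta_mode = "fixed"`.
#' @param cox_reid use the Cox-Reid adjusted likelihood for theta estimation.
#' @param chunk_size genes per chunk.
#' @return list of `gene_fit` objects (with `$theta_est` attached when
#'   estimated), in input gene order.
#' @export
fit_all_genes <- function(counts, X, size_factors = NULL,
                          theta_mode = c("estimate", "zero", "fixed"),
                          theta_values = NULL, cox_reid = TRUE,
                          chunk_size = 200L) {
  theta_mode <- match.arg(theta_mode)
  handle <- as_matrix_handle(counts)
  X <- check_design(X)
  if (handle$n_cells != nrow(X)) {
    stop("design has ", nrow(X), " rows but the matrix has ",
         handle$n_cells, " cells")
  }
  if (is.null(size_factors)) size_factors <- rep(1, handle$n_cells)
  if (length(size_factors) != handle$n_cells) {
    stop("`size_factors` must have one entry per cell")
  }
  if (theta_mode == "fixed") {
    if (is.null(theta_values)) stop("`theta_values` required for theta_mode = \"fixed\"")
    theta_values <- rep_len(theta_values, handle$n_genes)
  }
  offsets <- log(size_factors)

  fits <- vector("list", handle$n_genes)
  it <- chunk_iterator(handle, chunk_size)
  repeat {
    ch <- it()
    if (is.null(ch)) break
    for (j in seq_along(ch$rows)) {
      g <- ch$rows[j]
      y <- ch$counts[j, ]
      fits[[g]] <- switch(theta_mode,
        zero = fit_beta(y, X, offsets, theta = 0),
        fixed = fit_beta(y, X, offsets, theta = theta_values[g]),
        estimate = fit_gene(y, X, size_factors, cox_reid = cox_reid))
    }
  }
  names(fits) <- handle$gene_names
  fits
}
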