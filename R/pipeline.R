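# High-level user interface: gp_fit() fits every gene of a count matrix and
# gp_test_de() runs the quasi-likelihood F-test between nested designs.

#' Fit Gamma-Poisson GLMs to every gene of a count matrix
#'
#' For each gene, fits `log mu = X beta + log s` by iteratively reweighted
#' least squares and (by default) estimates the overdispersion theta by
#' Cox-Reid adjusted maximum likelihood over the bundled count representation,
#' then smooths theta against mean expression with a running-median trend.
#'
#' @param counts gene x cell matrix of non-negative integers, or a
#'   `matrix_handle` from [read_matrix()] (possibly on-disk).
#' @param design design matrix (cells x p), or a one-sided formula evaluated
#'   on `col_data` with treatment coding (factor levels ordered by first
#'   appearance, first level = reference).
#' @param col_data per-cell covariate data.frame (required when `design` is a
#'   formula).
#' @param size_factors `"normed-sum"` (default), `"median-of-ratios"`, or a
#'   numeric vector of per-cell factors.
#' @param theta `"estimate"` (default), `"zero"` for the Poisson fast path, or
#'   a numeric vector of fixed per-gene overdispersions.
#' @param cox_reid use the Cox-Reid adjustment during theta estimation.
#' @param chunk_size genes per streamed chunk.
#' @return a `gp_fit` object; see [tidy.gp_fit()] for the per-gene table.
#' @examples
#' sim <- simulate_counts(30, 40, X = two_group_design(40),
#'                        beta = cbind(log(4), c(rep(0, 15), rep(1, 15))),
#'                        theta = 0.2, seed = 7)
#' fit <- gp_fit(sim$counts, sim$X, size_factors = sim$size_factors)
#' fit
#' @export
gp_fit <- function(counts, design = NULL, col_data = NULL,
                   size_factors = "normed-sum",
                   theta = "estimate", cox_reid = TRUE, chunk_size = 200L) {
  handle <- as_matrix_handle_lazy(counts)
  X <- build_design(design, col_data, handle)
  X <- check_design(X)
  sf <- resolve_size_factors(size_factors, handle, chunk_size)

  theta_mode <- if (is.character(theta)) match.arg(theta, c("estimate", "zero")) else "fixed"
  fits <- fit_all_genes(handle, X, size_factors = sf,
                        theta_mode = theta_mode,
                        theta_values = if (theta_mode == "fixed") theta else NULL,
                        cox_reid = cox_reid, chunk_size = chunk_size)

  theta_hat <- vapply(fits, function(f) f$theta_est %||% f$theta_used, 1.0)
  mean_expr <- vapply(fits, function(f) mean(f$mu / sf), 1.0)
  theta_trend <- if (theta_mode == "estimate" && handle$n_genes >= 2L) {
    fit_trend(theta_hat, mean_expr)
  } else theta_hat

  structure(list(
    handle = handle, design = X, col_data = col_data,
    size_factors = sf, offsets = log(sf),
    beta = do.call(rbind, lapply(fits, function(f) unname(f$beta))),
    theta = unname(theta_hat), theta_trend = unname(theta_trend),
    mean_expression = unname(mean_expr),
    deviance = vapply(fits, `[[`, 1.0, "deviance"),
    df_residual = fits[[1]]$df_residual,
    iterations = vapply(fits, `[[`, 1L, "iterations"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    flags = vapply(fits, function(f) paste(f$flags, collapse = ";"), ""),
    theta_mode = theta_mode, cox_reid = cox_reid,
    chunk_size = chunk_size,
    gene_names = handle$gene_names), class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> ", length(x$gene_names), " genes x ", x$handle$n_cells,
      " cells; design: ", paste(colnames(x$design), collapse = " + "),
      "\n  theta mode: ", x$theta_mode,
      if (x$theta_mode == "estimate") paste0(" (Cox-Reid ", if (x$cox_reid) "on" else "off", ")"),
      "; converged: ", sum(x$converged), "/", length(x$converged), "\n", sep = "")
  invisible(x)
}

build_design <- function(design, col_data, handle) {
  if (is.null(design)) {
    return(matrix(1, handle$n_cells, 1, dimnames = list(NULL, "intercept")))
  }
  if (inherits(design, "formula")) {
    if (is.null(col_data)) stop("`col_data` is required when `design` is a formula")
    col_data <- as.data.frame(col_data)
    if (nrow(col_data) != handle$n_cells) {
      stop("`col_data` must have one row per cell")
    }
    # treatment coding with factor levels in first-appearance order
    for (nm in names(col_data)) {
      if (is.character(col_data[[nm]])) {
        col_data[[nm]] <- factor(col_data[[nm]], levels = unique(col_data[[nm]]))
      }
    }
    return(stats::model.matrix(design, data = col_data))
  }
  as.matrix(design)
}

resolve_size_factors <- function(size_factors, handle, chunk_size) {
  if (is.numeric(size_factors)) {
    if (length(size_factors) != handle$n_cells) {
      stop("`size_factors` must have one entry per cell")
    }
    if (any(size_factors <= 0)) stop("size factors must be positive")
    return(as.numeric(size_factors))
  }
  method <- match.arg(size_factors, c("normed-sum", "median-of-ratios"))
  if (method == "normed-sum") {
    csums <- stream_colsums(handle, chunk_size)
    if (any(csums == 0)) {
      stop("cell(s) ", paste(which(csums == 0), collapse = ", "),
           " have all-zero counts; size factors are undefined")
    }
    recenter_geomean(csums)
  } else {
    if (handle$backend == "on-disk") {
      stop("median-of-ratios size factors need the in-memory backend; ",
           "use \"normed-sum\" or supply factors")
    }
    as.numeric(estimate_size_factors(read_chunk(handle, seq_len(handle$n_genes)),
                                     "median-of-ratios"))
  }
}

#' Quasi-likelihood differential expression test
#'
#' Refits the full and a nested reduced model for every gene at the trended
#' overdispersion, forms gene-wise quasi-dispersions `deviance / df`, shrinks
#' them toward a common prior location with an empirically estimated prior df
#' (moment matching of `log sigma^2` to a scaled F distribution), and tests
#' the dropped coefficients with the quasi-likelihood F statistic
#' `F = (deviance drop / df1) / sigma2_shrunk` on
#' `F(df1, df_prior + df_residual)`.
#'
#' @param fit a `gp_fit` object (with `theta = "estimate"` or fixed theta).
#' @param reduced reduced design: a formula (evaluated on the fit's
#'   `col_data`), a design matrix, or a character vector of full-design
#'   column names to keep. Its column span must be a subspace of the full
#'   design's.
#' @param contrast coefficient whose log2 fold change to report: a column
#'   name of the full design or a numeric contrast vector. Defaults to the
#'   (single) dropped coefficient when unambiguous.
#' @param shrink use empirical-Bayes shrinkage (default). `FALSE` tests with
#'   gene-wise quasi-dispersions and infinite-prior handling off (plain QL).
#' @param use_trended_theta refit at the trended theta (default); `FALSE`
#'   uses the gene-wise estimates instead.
#' @return tibble with one row per gene: `gene`, `lfc`, `f_statistic`, `df1`,
#'   `df2`, `pval`, `padj`, `converged`.
#' @export
gp_test_de <- function(fit, reduced, contrast = NULL, shrink = TRUE,
                       use_trended_theta = TRUE) {
  stopifnot(inherits(fit, "gp_fit"))
  X <- fit$design
  Xr <- reduced_design(reduced, fit)
  check_nested(X, Xr)
  df1 <- ncol(X) - ncol(Xr)
  if (df1 < 1L) stop("reduced design must drop at least one coefficient")
  contrast <- resolve_contrast(contrast, X, Xr)

  theta_vec <- if (use_trended_theta) fit$theta_trend else fit$theta
  G <- length(fit$gene_names)
  full <- vector("list", G); red <- vector("list", G)
  it <- chunk_iterator(fit$handle, fit$chunk_size)
  repeat {
    ch <- it()
    if (is.null(ch)) break
    for (j in seq_along(ch$rows)) {
      g <- ch$rows[j]
      y <- ch$counts[j, ]
      full[[g]] <- fit_beta(y, X, fit$offsets, theta = theta_vec[g],
                            beta_init = fit$beta[g, ])
      red[[g]] <- fit_beta(y, Xr, fit$offsets, theta = theta_vec[g])
    }
  }

  sigma2 <- vapply(full, quasi_dispersion, 1.0)
  df_res <- full[[1]]$df_residual
  if (shrink) {
    prior <- estimate_ql_prior(sigma2, df_res)
    sigma2_use <- shrink_quasi_dispersions(sigma2, prior, df_res)
    df_prior <- prior$df_prior
  } else {
    sigma2_use <- sigma2
    df_prior <- 0
  }

  rows <- lapply(seq_len(G), function(g) {
    ts <- ql_f_test(full[[g]], red[[g]], sigma2_use[g], df_prior)
    ts$lfc <- contrast_lfc(full[[g]], contrast)
    ts$converged <- full[[g]]$converged && red[[g]]$converged
    ts
  })
  tbl <- tibble::tibble(
    gene = fit$gene_names,
    lfc = vapply(rows, `[[`, 1.0, "lfc"),
    f_statistic = vapply(rows, `[[`, 1.0, "f_statistic"),
    df1 = vapply(rows, function(r) as.numeric(r$df1), 1.0),
    df2 = vapply(rows, function(r) as.numeric(r$df2), 1.0),
    pval = vapply(rows, `[[`, 1.0, "pval"),
    converged = vapply(rows, `[[`, TRUE, "converged"))
  tbl$padj <- bh_adjust(tbl$pval)
  tbl[, c("gene", "lfc", "f_statistic", "df1", "df2", "pval", "padj", "converged")]
}

reduced_design <- function(reduced, fit) {
  if (inherits(reduced, "formula")) {
    build_design(reduced, fit$col_data, fit$handle)
  } else if (is.character(reduced)) {
    missing_cols <- setdiff(reduced, colnames(fit$design))
    if (length(missing_cols)) {
      stop("reduced design names not in the full design: ",
           paste(missing_cols, collapse = ", "))
    }
    fit$design[, reduced, drop = FALSE]
  } else {
    as.matrix(reduced)
  }
}

check_nested <- function(X, Xr) {
  if (nrow(Xr) != nrow(X)) stop("designs must describe the same cells")
  # every reduced column must lie in the span of the full design
  resid <- Xr - X %*% qr.coef(qr(X), Xr)
  resid[is.na(resid)] <- Inf
  if (max(abs(resid)) > 1e-8 * max(1, max(abs(Xr)))) {
    stop("reduced design is not nested in the full design")
  }
  invisible(TRUE)
}

resolve_contrast <- function(contrast, X, Xr) {
  p <- ncol(X)
  if (is.null(contrast)) {
    dropped <- setdiff(colnames(X), colnames(Xr))
    if (length(dropped) != 1L) {
      stop("`contrast` must be given when the test drops ", length(dropped),
           " coefficients")
    }
    contrast <- dropped
  }
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X)) {
      stop("contrast `", contrast, "` is not a design column")
    }
    as.numeric(colnames(X) == contrast)
  } else {
    if (length(contrast) != p) stop("numeric contrast must have length ", p)
    as.numeric(contrast)
  }
}
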