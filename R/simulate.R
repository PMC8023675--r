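# Synthetic Gamma-Poisson data with known ground truth. Counts are drawn by
# the generative two-step — a Gamma-distributed rate with mean mu and shape
# 1/theta, then a Poisson draw — so the simulated variance is exactly
# mu + theta * mu^2; theta = 0 draws directly from the Poisson to avoid the
# degenerate Gamma. Each gene uses a seed derived deterministically from the
# global seed and the gene index, so gene order, chunking and subsetting never
# change the draws of any other gene.

#' Simulate a Gamma-Poisson count matrix with known truth
#'
#' Generates `y_gc ~ GammaPoisson(mu_gc, theta_g)` with
#' `mu_gc = sf_c * exp((X beta_g)_c)`.
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param X design matrix (cells x p), or `NULL` for intercept-only. For a
#'   simple two-group design use [two_group_design()].
#' @param beta genes x p coefficient matrix (log scale); a vector is recycled
#'   across genes for p = 1.
#' @param theta per-gene overdispersion: a single value, a vector of length
#'   `n_genes`, or a function of the per-gene mean expression
#'   (mean-dependent dispersion).
#' @param sf_log_sd standard deviation of log size factors (log-normal,
#'   re-centered to geometric mean 1); 0 gives all-1 factors.
#' @param size_factors optional explicit size factors (overrides
#'   `sf_log_sd`).
#' @param seed integer seed; fully determines the output.
#' @return list with `counts` (named gene x cell integer matrix), `X`,
#'   `size_factors`, and `truth` (list with `beta`, `theta`, `size_factors`).
#' @export
simulate_counts <- function(n_genes, n_cells, X = NULL, beta, theta = 0,
                            sf_log_sd = 0, size_factors = NULL, seed = 1L) {
  if (n_genes < 1L || n_cells < 1L) stop("need at least one gene and one cell")
  if (is.null(X)) X <- matrix(1, n_cells, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (nrow(X) != n_cells) stop("X must have n_cells rows")
  p <- ncol(X)
  beta <- if (is.matrix(beta)) beta else matrix(rep_len(beta, n_genes * p),
                                                n_genes, p, byrow = p > 1)
  if (nrow(beta) == 1L && n_genes > 1L) {
    beta <- beta[rep(1L, n_genes), , drop = FALSE]  # shared coefficients
  }
  if (nrow(beta) != n_genes || ncol(beta) != p) {
    stop("beta must be an n_genes x ncol(X) matrix")
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(size_factors)) {
    size_factors <- if (sf_log_sd > 0) {
      recenter_geomean(exp(stats::rnorm(n_cells, 0, sf_log_sd)))
    } else rep(1, n_cells)
  }
  if (any(size_factors <= 0)) stop("size factors must be positive")

  eta0 <- tcrossprod(beta, X)  # genes x cells linear predictor sans offset
  mu <- sweep(exp(eta0), 2, size_factors, `*`)

  theta_g <- if (is.function(theta)) theta(rowMeans(mu)) else rep_len(theta, n_genes)
  if (any(theta_g < 0)) stop("theta must be non-negative")

  counts <- matrix(0L, n_genes, n_cells)
  for (g in seq_len(n_genes)) {
    set.seed(gene_seed(seed, g))
    counts[g, ] <- draw_gp(mu[g, ], theta_g[g])
  }
  dimnames(counts) <- list(sprintf("gene_%04d", seq_len(n_genes)),
                           sprintf("cell_%04d", seq_len(n_cells)))
  list(counts = counts, X = X, size_factors = size_factors,
       truth = list(beta = beta, theta = theta_g, size_factors = size_factors))
}

# counter-based per-gene seed below 2^31
gene_seed <- function(seed, g) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(g) * 2654435761) %% 2147483647)
}

draw_gp <- function(mu, theta) {
  if (theta == 0) {
    stats::rpois(length(mu), mu)
  } else {
    rate <- stats::rgamma(length(mu), shape = 1 / theta, scale = theta * mu)
    stats::rpois(length(mu), rate)
  }
}

#' Two-group one-hot design matrix
#'
#' Intercept plus indicator of the second group; cells split evenly (first
#' half group A) unless `group` is given.
#'
#' @param n_cells number of cells.
#' @param group optional logical/0-1 vector marking group B membership.
#' @return design matrix with columns `intercept`, `groupB`.
#' @export
two_group_design <- function(n_cells, group = NULL) {
  if (is.null(group)) group <- seq_len(n_cells) > n_cells / 2
  cbind(intercept = 1, groupB = as.numeric(group))
}

#' Write the canonical fixture suite
#'
#' Deterministically generates the small round-trip fixtures and the
#' differential-expression / null simulation fixtures used across the test
#' surfaces, with ground-truth TSVs:
#' \itemize{
#'   \item `small.mtx` (+ `features.tsv`, `barcodes.tsv`) and `small.h5`:
#'     a 20 gene x 12 cell matrix.
#'   \item `de_counts.tsv`, `de_metadata.tsv`, `de_truth.tsv`: two balanced
#'     groups, 10\% non-null genes at log2 fold change 1.
#'   \item `null_counts.tsv`, `null_metadata.tsv`, `null_truth.tsv`: the same
#'     design with no differential genes.
#'   \item `manifest.tsv`: the file list.
#' }
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_genes,n_cells size of the DE and null fixtures.
#' @param theta overdispersion of the DE/null fixtures.
#' @return tibble manifest of written files, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, n_genes = 300L,
                               n_cells = 200L, theta = 0.3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  sm <- simulate_counts(20, 12, beta = log(5), theta = 0.4, sf_log_sd = 0.2,
                        seed = gene_seed(seed, 101L))
  write_mtx(sm$counts, file.path(out_dir, "small.mtx"))
  write_10x_h5(sm$counts, file.path(out_dir, "small.h5"))
  written <- c(written, "small.mtx", "features.tsv", "barcodes.tsv", "small.h5")

  for (kind in c("de", "null")) {
    X <- two_group_design(n_cells)
    n_de <- if (kind == "de") round(0.10 * n_genes) else 0L
    lfc <- rep(0, n_genes)
    if (n_de > 0) {
      set.seed(gene_seed(seed, 202L))
      de_idx <- sample.int(n_genes, n_de)
      lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)  # |LFC| = 1
    }
    set.seed(gene_seed(seed, 203L))
    base <- stats::rnorm(n_genes, log(5), 0.8)
    beta <- cbind(intercept = base, groupB = lfc * log(2))
    sim <- simulate_counts(n_genes, n_cells, X = X, beta = beta, theta = theta,
                           sf_log_sd = 0.3, seed = gene_seed(seed, if (kind == "de") 1L else 2L))
    cdf <- data.frame(gene = rownames(sim$counts), sim$counts, check.names = FALSE)
    write_results(cdf, file.path(out_dir, paste0(kind, "_counts.tsv")))
    write_results(data.frame(cell = colnames(sim$counts),
                             group = ifelse(X[, "groupB"] == 1, "B", "A"),
                             size_factor = sim$size_factors),
                  file.path(out_dir, paste0(kind, "_metadata.tsv")))
    write_results(data.frame(gene = rownames(sim$counts),
                             beta_intercept = beta[, 1], lfc = lfc,
                             theta = sim$truth$theta,
                             is_de = lfc != 0),
                  file.path(out_dir, paste0(kind, "_truth.tsv")))
    written <- c(written, paste0(kind, c("_counts.tsv", "_metadata.tsv", "_truth.tsv")))
  }

  manifest <- tibble::tibble(file = written)
  write_results(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
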