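#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-gene coefficient and dispersion table of a fit
#'
#' One row per gene with the estimated coefficients (one `beta_*` column per
#' design column), the gene-wise and trended overdispersion, mean expression,
#' deviance, residual df and convergence information.
#'
#' @param x a `gp_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy gp_fit
#' @export
tidy.gp_fit <- function(x, ...) {
  beta <- as.data.frame(x$beta)
  names(beta) <- paste0("beta_", colnames(x$design))
  tibble::as_tibble(cbind(
    data.frame(gene = x$gene_names, stringsAsFactors = FALSE),
    beta,
    data.frame(theta = x$theta, theta_trend = x$theta_trend,
               mean_expression = x$mean_expression,
               deviance = unname(x$deviance), df_residual = x$df_residual,
               iterations = unname(x$iterations),
               converged = unname(x$converged), flags = unname(x$flags))))
}

#' One-row summary of a fit
#'
#' @param x a `gp_fit`.
#' @param ... unused.
#' @return a tibble with gene/cell counts, coefficient count, median theta,
#'   total deviance and the fraction of converged genes.
#' @method glance gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_names),
    n_cells = x$handle$n_cells,
    n_coef = ncol(x$design),
    median_theta = stats::median(x$theta),
    total_deviance = sum(x$deviance),
    prop_converged = mean(x$converged))
}

#' Dispersion-mean diagnostic plot
#'
#' Gene-wise overdispersion estimates against mean expression with the
#' running-median trend overlaid; both axes on log scale (zero estimates are
#' shown at the axis floor).
#'
#' @param object a `gp_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gp_fit
#' @export
autoplot.gp_fit <- function(object, ...) {
  d <- tidy(object)
  d$theta_floor <- pmax(d$theta, 1e-8)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_expression)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$theta_floor),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theta_trend), color = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean expression", y = "overdispersion (theta)",
                  title = "Gene-wise overdispersion and trend")
}

#' P-value histogram of a differential-expression table
#'
#' Under the null the p-values are uniform; enrichment near zero indicates
#' signal.
#'
#' @param de_table tibble from [gp_test_de()].
#' @param bins number of histogram bins.
#' @return a ggplot object.
#' @export
plot_pvalue_histogram <- function(de_table, bins = 40) {
  ggplot2::ggplot(de_table, ggplot2::aes(x = .data$pval)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey70", color = "grey30") +
    ggplot2::labs(x = "p-value", y = "genes", title = "QL F-test p-values")
}

#' @importFrom rlang .data
NULL
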