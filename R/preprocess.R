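#' Estimate per-cell size factors
#'
#' Size factors capture differences in sequencing depth between cells and enter
#' the GLM as offsets `log(s_c)` on the linear predictor; counts are never
#' divided by them. After estimation the factors are re-centered so their
#' geometric mean is exactly 1, which makes the intercept interpretable as the
#' log mean expression of a typical cell.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"normed-sum"`}{`s_c` proportional to the column (cell) sum. Robust
#'     in the many-zero single-cell regime; the default.}
#'   \item{`"median-of-ratios"`}{`s_c` is the median over genes of
#'     `count[g, c] / geomean_g`, where `geomean_g` is the geometric mean of
#'     gene `g` across cells, taken over genes with all-positive counts. If no
#'     such gene exists the function falls back to `"normed-sum"` with a
#'     warning. Intended for bulk-like or pseudobulk matrices.}
#' }
#'
#' @param counts gene x cell matrix of non-negative integer counts (dense or
#'   `Matrix` sparse).
#' @param method `"normed-sum"` (default), `"median-of-ratios"`, or `"user"`.
#' @param user_factors positive per-cell factors, required for
#'   `method = "user"`; passed through unchanged after a positivity check.
#' @return numeric vector of positive size factors, one per cell, with
#'   geometric mean 1 (except `"user"`, which is not re-centered), and the
#'   method recorded in attribute `"method"`.
#' @export
estimate_size_factors <- function(counts,
                                  method = c("normed-sum", "median-of-ratios", "user"),
                                  user_factors = NULL) {
  method <- match.arg(method)
  if (method == "user") {
    if (is.null(user_factors)) stop("`user_factors` required for method = \"user\"")
    if (any(!is.finite(user_factors)) || any(user_factors <= 0)) {
      stop("user size factors must be positive and finite")
    }
    return(structure(as.numeric(user_factors), method = "user"))
  }
  counts <- as.matrix(counts)
  csums <- colSums(counts)
  if (any(csums == 0)) {
    stop("cell(s) ", paste(which(csums == 0), collapse = ", "),
         " have all-zero counts; size factors are undefined")
  }
  if (method == "median-of-ratios") {
    all_pos <- rowSums(counts == 0) == 0
    if (!any(all_pos)) {
      warning("no gene has all-positive counts; falling back to normed-sum size factors")
      method <- "normed-sum"
    } else {
      ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
      s <- apply(counts[all_pos, , drop = FALSE] / ref, 2, stats::median)
      if (any(s <= 0)) {
        warning("non-positive median-of-ratios factor; falling back to normed-sum")
        method <- "normed-sum"
      } else {
        return(structure(recenter_geomean(s), method = "median-of-ratios"))
      }
    }
  }
  structure(recenter_geomean(csums), method = "normed-sum")
}

recenter_geomean <- function(s) {
  as.numeric(s / exp(mean(log(s))))
}

#' Aggregate single cells into pseudobulk samples
#'
#' Sums counts over cells that share a sample label, producing one column per
#' biological replicate. Summing before testing is an effective way to assess
#' differential expression between samples in replicated single-cell designs,
#' because cells from the same sample are not independent replicates.
#'
#' @param counts gene x cell matrix of non-negative integers.
#' @param grouping sample label per cell (character or factor, length =
#'   number of cells).
#' @param col_data optional per-cell covariate table (data.frame). Every
#'   covariate must be constant within each label; the aggregated table has one
#'   row per sample.
#' @return list with `counts` (gene x sample integer matrix, samples in
#'   first-appearance order of the labels), `col_data` (aggregated covariates
#'   plus a `n_cells` column), and `grouping`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3), g2 = c(0, 1, 0))
#' pseudobulk(m, grouping = c("a", "a", "b"))$counts
#' @export
pseudobulk <- function(counts, grouping, col_data = NULL) {
  counts <- as.matrix(counts)
  if (length(grouping) != ncol(counts)) {
    stop("`grouping` must assign a label to each of the ", ncol(counts), " cells")
  }
  grouping <- as.character(grouping)
  if (anyNA(grouping)) stop("`grouping` may not contain missing labels")
  labels <- unique(grouping)  # first-appearance order
  g <- factor(grouping, levels = labels)
  agg <- t(rowsum(t(counts), g, reorder = FALSE))
  colnames(agg) <- labels

  agg_cd <- data.frame(row.names = labels)
  if (!is.null(col_data)) {
    col_data <- as.data.frame(col_data)
    if (nrow(col_data) != ncol(counts)) {
      stop("`col_data` must have one row per cell")
    }
    for (nm in names(col_data)) {
      n_vals <- vapply(split(col_data[[nm]], g), function(v) length(unique(v)), 1L)
      bad <- names(n_vals)[n_vals > 1L]
      if (length(bad)) {
        stop("covariate `", nm, "` varies within label(s): ",
             paste(bad, collapse = ", "))
      }
      agg_cd[[nm]] <- col_data[[nm]][match(labels, grouping)]
    }
  }
  agg_cd$n_cells <- as.integer(table(g)[labels])
  list(counts = agg, col_data = agg_cd, grouping = grouping)
}
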