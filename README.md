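# gpglm

Gamma-Poisson (negative binomial) generalized linear models for gene × cell
count matrices, aimed at single-cell RNA-seq differential expression.

Sequencing counts for a gene across replicate-like cells are well described by
`y ~ GammaPoisson(mu, theta)`, with mean `mu` and variance `mu + theta mu^2`;
`theta = 0` is the Poisson case and larger `theta` gives wider distributions.
Biological structure enters through a log-linear model with per-cell size
factors `s_c` as offsets:

```
log mu_gc = (X beta_g)_c + log s_c
```

For every gene, `gpglm`:

1. estimates `beta_g` by deviance-minimizing iteratively reweighted least
   squares (with step-halving and a Poisson fast path for `theta = 0`);
2. estimates `theta_g` by maximum likelihood (optionally Cox-Reid adjusted),
   evaluating the likelihood over a *bundled* representation of the repeated
   small counts — most entries of a single-cell matrix come from a small set
   of integers, so the per-gene likelihood collapses to a short weighted sum
   that is exactly, not approximately, equal to the dense evaluation;
3. smooths `theta` against mean expression with a running-median trend;
4. tests nested designs with a quasi-likelihood F-test: gene-wise
   quasi-dispersions `sigma^2_g = deviance / df` (at the trended `theta`) are
   shrunk toward a common location with an empirically estimated prior df
   (moment matching of `log sigma^2` to a scaled F distribution), and

   ```
   F_g = [(dev_reduced - dev_full) / df1] / sigma^2_shrunk  ~  F(df1, df_prior + df_residual)
   ```

Counts can be read from MatrixMarket, 10x-style HDF5 or TSV, and fitting
streams over contiguous gene chunks, so the full matrix never has to be in
memory; results are identical for any chunk size and backend. Pseudobulk
aggregation (summing cells within biological replicates before testing) is
built in.

## Worked example

Simulate 100 genes × 120 cells in two groups of 60, with the first 10 genes
up-regulated two-fold (log2 fold change 1) and overdispersion 0.3, then fit
and test:

```r
library(gpglm)

sim <- simulate_counts(n_genes = 100, n_cells = 120,
                       X = two_group_design(120),
                       beta = cbind(rnorm(100, log(5), 0.6),
                                    c(rep(log(2), 10), rep(0, 90))),
                       theta = 0.3, sf_log_sd = 0.3, seed = 14)

fit <- gp_fit(sim$counts, sim$X, size_factors = sim$size_factors)
fit
#> <gp_fit> 100 genes x 120 cells; design: intercept + groupB
#>   theta mode: estimate (Cox-Reid on); converged: 100/100

glance(fit)
#> # A tibble: 1 × 6
#>   n_genes n_cells n_coef median_theta total_deviance prop_converged
#> 1     100     120      2        0.285         12895.              1

res <- gp_test_de(fit, reduced = "intercept", contrast = "groupB")
head(res[order(res$pval), ], 5)
#> # A tibble: 5 × 8
#>   gene        lfc f_statistic   df1   df2     pval     padj converged
#> 1 gene_0006 1.26         60.2     1   Inf 8.69e-15 8.69e-13 TRUE
#> 2 gene_0010 1.09         45.4     1   Inf 1.62e-11 8.12e-10 TRUE
#> 3 gene_0004 0.986        38.9     1   Inf 4.43e-10 1.42e- 8 TRUE
#> 4 gene_0001 1.15         38.4     1   Inf 5.69e-10 1.42e- 8 TRUE
#> 5 gene_0007 1.02         36.9     1   Inf 1.27e- 9 2.54e- 8 TRUE

sum(res$padj < 0.05)
#> [1] 10
```

The estimated median overdispersion (0.285) sits near the simulated 0.3, the
reported `lfc` of the true positives is near the simulated value of 1, and at
a Benjamini-Hochberg threshold of 0.05 exactly the ten genes simulated as
differential are called. `df2 = Inf` indicates that the empirical-Bayes prior
collapsed to a point (no gene-level variability beyond the trend), so the F
reference reduces to its chi-square limit. `tidy(fit)` gives the per-gene
coefficient/dispersion table and `autoplot(fit)` the dispersion–mean trend.

## Command line

The same pipeline is available as a thin Rscript front end:

```sh
Rscript exec/gpglm fit  --counts counts.mtx --design-formula "~group" \
    --metadata cells.tsv --out fit.tsv
Rscript exec/gpglm test --counts counts.mtx --design-formula "~group" \
    --metadata cells.tsv --reduced "~1" --pseudobulk sample --out de.tsv
```

Outputs are deterministic TSVs whose `#` header records the package version,
the resolved options and the seed. Exit codes: 0 success, 1 runtime failure,
2 validation failure.

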