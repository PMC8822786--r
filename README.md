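# scstab

Stability-based estimation of the number of cell types in single-cell
RNA-seq data, with the benchmark machinery to evaluate such estimators.

## The problem

Clustering cells into cell types requires choosing `k`, the number of
clusters — and when clusters are interpreted as cell types, `k` is a
biological claim. `scstab` estimates `k` from the data by **clustering
stability**: if a dataset truly contains `k` separable populations, then
clusterings computed on different random views of the genes should agree
at that `k`, and disagree at the wrong `k`.

## The estimator

For each candidate `k` in a grid (default `2:25`), build an ensemble of
`B` clusterings (default 20). Member `b`:

1. projects the log-normalised matrix onto a random gene subset,
2. encodes the projected cells to `d` dimensions (autoencoder, or
   truncated PCA as a fast deterministic fallback),
3. clusters the encoding into `k` groups (k-means by default; any base
   clusterer can be plugged in).

The stability score at `k` is the **median pairwise NMI** over all
`B(B-1)/2` member pairs,

```
stability(k) = median{ NMI(P_a, P_b) : 1 <= a < b <= B },
NMI(U, V)    = 2 I(U;V) / (H(U) + H(V)),
```

and the estimate is `k_hat = argmax_k stability(k)` (ties to the smallest
`k`). The returned partition is a consensus: average-linkage hierarchical
clustering of `1 −` co-association, cut at `k_hat`.

Around the estimator the package provides the standard benchmark
apparatus: a negative-binomial simulator of labelled cell-type pools
(`simulate_pool()`), the >300-cells-per-type selection-pool filter
(`filter_pool()`), a four-setting subsampling design expanding to
160/200/60/80 datasets (`enumerate_design()`, `sample_dataset()`),
pair-counting concordance metrics — ARI, NMI, Fowlkes–Mallows, Jaccard —
(`concordance_scores()`), deviation statistics (`deviation_stats()`), a
good/intermediate/poor performance rubric (`summarise_performance()`),
and an end-to-end runner (`run_benchmark()`).

## Worked example

```r
library(scstab)

pool <- simulate_pool(sim_pool_spec(
  n_types = 3, cells_per_type = 100, n_genes = 500,
  n_marker_genes_per_type = 20, separation = 4, seed = 1))
pool
#> <count_matrix> 500 genes x 300 cells; 3 cell types
#>   nonzero entries: 119125 (79.4%)

nm  <- log_normalise(pool)
est <- estimate_k(nm,
                  ensemble_config(B = 8, encoder = "pca_fallback",
                                  encode_dim = 8, seed = 1),
                  k_grid = 2:8)
est
#> <scstab_estimate> k_hat = 3 (stability 0.966, median of pairwise NMI over B = 8 members)
#>   grid: 2 .. 8

tidy(est)
#> # A tibble: 7 x 3
#>       k score is_k_hat
#>   <int> <dbl> <lgl>
#> 1     2 0.277 FALSE
#> 2     3 0.966 TRUE
#> 3     4 0.811 FALSE
#> 4     5 0.686 FALSE
#> 5     6 0.599 FALSE
#> 6     7 0.570 FALSE
#> 7     8 0.536 FALSE

concordance_scores(pool$labels, est$consensus)
#> # A tibble: 1 x 4
#>     ari   nmi    fm jaccard
#>   <dbl> <dbl> <dbl>   <dbl>
#> 1     1     1     1       1
```

Three simulated cell types: stability peaks sharply at `k = 3`
(score 0.966 vs 0.277 at `k = 2` — splitting real structure — and a
decaying tail for `k > 3` — fragmenting it). The consensus partition at
`k_hat` matches the simulated labels exactly (all four concordance
indices are 1). `ggplot2::autoplot(est)` draws the profile;
`glance(est)` gives a one-row summary.

A command-line wrapper with `simulate`, `design`, `estimate-k`,
`evaluate`, `benchmark` and `summarise` subcommands is installed at
`system.file("scripts", "scstab", package = "scstab")`.

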