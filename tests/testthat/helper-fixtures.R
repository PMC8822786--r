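# Shared fixtures and independent oracles, all built in code.

# Small well-separated labelled pool for pipeline tests.
make_test_pool <- function(n_types = 3, cells_per_type = 100, n_genes = 300,
                           separation = 4, dispersion = 0.2, seed = 1,
                           n_marker = 20) {
  n_marker <- min(n_marker, n_genes %/% (2 * n_types))
  simulate_pool(sim_pool_spec(
    n_types = n_types, cells_per_type = cells_per_type, n_genes = n_genes,
    n_marker_genes_per_type = n_marker, separation = separation,
    dispersion = dispersion, seed = seed))
}

# Brute-force pair-count oracle: enumerate every unordered pair.
brute_pair_counts <- function(u, v) {
  n <- length(u)
  counts <- c(n11 = 0, n00 = 0, n01 = 0, n10 = 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_u <- u[i] == u[j]
      same_v <- v[i] == v[j]
      key <- if (same_u && same_v) "n11" else if (!same_u && !same_v) "n00"
             else if (same_u) "n01" else "n10"
      counts[key] <- counts[key] + 1
    }
  }
  counts
}

# A fast deterministic ensemble configuration for tests.
fast_config <- function(k = 2, B = 4, seed = 1, ...) {
  ensemble_config(B = B, projection_fraction = 0.5, encode_dim = 5,
                  encoder = "pca_fallback", k = k, seed = seed, ...)
}

random_partition <- function(n, max_k = 4) {
  sample.int(sample.int(max_k, 1), n, replace = TRUE)
}
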