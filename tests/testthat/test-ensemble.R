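test_that("random projection samples the stated number of genes", {
  nm <- log_normalise(make_test_pool(2, 20, n_genes = 500))
  full <- random_projection(nm, 1, member_seed = 1)
  expect_identical(full$gene_ids, nm$gene_ids)
  half <- random_projection(nm, 0.5, member_seed = 1)
  expect_equal(nrow(half$values), 250)
  expect_true(all(half$gene_ids %in% nm$gene_ids))
  expect_identical(random_projection(nm, 0.5, member_seed = 1)$gene_ids,
                   half$gene_ids)
  other <- random_projection(nm, 0.5, member_seed = 2)
  expect_false(identical(half$gene_ids, other$gene_ids))
})

test_that("projection enforces the encoder-feasibility floor", {
  nm <- log_normalise(make_test_pool(2, 20, n_genes = 40))
  floored <- random_projection(nm, 0.1, member_seed = 1, encode_dim = 10)
  expect_equal(nrow(floored$values), 20)  # floor = 2 * encode_dim
  expect_error(random_projection(nm, 0.1, member_seed = 1, encode_dim = 40),
               "not more than encode_dim")
  expect_error(random_projection(nm, 0, 1), "fraction")
})

test_that("encodings have the contracted shape and reject bad input", {
  nm <- log_normalise(make_test_pool(2, 25, n_genes = 60))
  E <- encode_cells(nm, encode_dim = 4, member_seed = 1,
                    encoder = "pca_fallback")
  expect_equal(dim(E), c(50, 4))
  expect_error(encode_cells(nm, encode_dim = 60), "smaller than")
  bad <- nm
  bad$values[1, 1] <- NaN
  expect_error(encode_cells(bad, 4, encoder = "pca_fallback"), "non-finite")
})

test_that("pca encoding of a rank-2 matrix reconstructs it exactly", {
  set.seed(9)
  basis <- matrix(rnorm(2 * 30), 2, 30)
  scores <- matrix(rnorm(40 * 2), 40, 2)
  X <- scores %*% basis  # cells x genes, rank 2
  nm <- structure(list(values = t(X), gene_ids = sprintf("g%d", 1:30),
                       cell_ids = sprintf("c%d", 1:40), labels = NULL,
                       pseudocount = 1, log_base = 2),
                  class = "normalized_matrix")
  E <- encode_cells(nm, encode_dim = 2, encoder = "pca_fallback")
  rec <- E %*% t(attr(E, "rotation")) +
    matrix(attr(E, "center"), 40, 30, byrow = TRUE)
  expect_lt(norm(rec - X, "F") / norm(X, "F"), 1e-6)
})

test_that("autoencoder encodings are seeded, deterministic and useful", {
  nm <- log_normalise(make_test_pool(2, 30, n_genes = 60, seed = 3))
  E1 <- encode_cells(nm, encode_dim = 4, epochs = 15, member_seed = 11,
                     encoder = "autoencoder")
  E2 <- encode_cells(nm, encode_dim = 4, epochs = 15, member_seed = 11,
                     encoder = "autoencoder")
  expect_identical(E1, E2)
  expect_equal(dim(E1), c(60, 4))
  E3 <- encode_cells(nm, encode_dim = 4, epochs = 15, member_seed = 12,
                     encoder = "autoencoder")
  expect_false(identical(E1, E3))
  # the encoding must still separate the two simulated types
  set.seed(1)
  km <- kmeans(E1, 2, nstart = 10)
  expect_gte(mclust::adjustedRandIndex(km$cluster, nm$labels), 0.9)
})

test_that("ensemble configuration rejects invalid settings", {
  expect_error(ensemble_config(B = 1), "at least 2")
  expect_error(ensemble_config(k = 1), "k must be at least 2")
  expect_error(ensemble_config(projection_fraction = 0), "projection_fraction")
  expect_error(ensemble_config(base_clusterer = "plugin"), "clusterer_fun")
})

test_that("a deterministic plugin clusterer yields a 0/1 coassociation", {
  nm <- log_normalise(make_test_pool(2, 20, n_genes = 60))
  cfg <- ensemble_config(
    B = 2, projection_fraction = 1, encode_dim = 5,
    encoder = "pca_fallback", base_clusterer = "plugin",
    clusterer_fun = function(E, k, seed) {
      withr::with_seed(1, kmeans(E, k, nstart = 5)$cluster)
    },
    k = 2, seed = 1)
  er <- run_ensemble(nm, cfg)
  expect_identical(er$members[[1]], er$members[[2]])
  expect_true(all(er$coassociation %in% c(0, 1)))
  expect_true(all(diag(er$coassociation) == 1))
})

test_that("coassociation counts conserve the members' within-cluster pairs", {
  nm <- log_normalise(make_test_pool(3, 12, n_genes = 80, seed = 2))
  cfg <- fast_config(k = 3, B = 5)
  er <- run_ensemble(nm, cfg)
  co <- er$coassociation
  ut <- upper.tri(co)
  # brute force: average the per-member pair indicator over all pairs
  manual <- Reduce(`+`, lapply(er$members, function(a) outer(a, a, `==`) * 1))
  manual <- manual / length(er$members)
  expect_equal(unname(co), manual, tolerance = 1e-12)
  expect_equal(sum(co[ut]),
               mean(vapply(er$members,
                           function(a) sum(choose(table(a), 2)), 1)),
               tolerance = 1e-9)
})

test_that("permuting cells permutes ensemble outputs consistently", {
  nm <- log_normalise(make_test_pool(2, 15, n_genes = 60, seed = 5))
  cfg <- ensemble_config(B = 3, projection_fraction = 1, encode_dim = 4,
                         encoder = "pca_fallback", base_clusterer = "plugin",
                         clusterer_fun = function(E, k, seed) {
                           # geometric rule, invariant to row order
                           as.integer(E[, 1] > stats::median(E[, 1])) + 1L
                         },
                         k = 2, seed = 7)
  er <- run_ensemble(nm, cfg)
  perm <- sample(seq_len(30))
  nm_p <- nm
  nm_p$values <- nm$values[, perm]
  nm_p$cell_ids <- nm$cell_ids[perm]
  nm_p$labels <- nm$labels[perm]
  er_p <- run_ensemble(nm_p, cfg)
  expect_equal(unname(er_p$coassociation),
               unname(er$coassociation[perm, perm]), tolerance = 1e-9)
})

test_that("consensus of identical members recovers the member partition", {
  nm <- log_normalise(make_test_pool(3, 25, n_genes = 90, seed = 4))
  cfg <- ensemble_config(B = 3, projection_fraction = 1, encode_dim = 6,
                         encoder = "pca_fallback", base_clusterer = "plugin",
                         clusterer_fun = function(E, k, seed) {
                           withr::with_seed(1, kmeans(E, k, nstart = 5)$cluster)
                         },
                         k = 3, seed = 1)
  er <- run_ensemble(nm, cfg)
  cons <- consensus_partition(er, 3)
  expect_equal(mclust::adjustedRandIndex(cons, er$members[[1]]), 1)
})

test_that("a coassociation identity matrix cuts to singletons", {
  er <- structure(list(members = list(1:6, 1:6),
                       coassociation = diag(6), config = NULL,
                       cell_ids = sprintf("c%d", 1:6)),
                  class = "ensemble_result")
  cons <- consensus_partition(er, 6)
  expect_equal(length(unique(cons)), 6)
  expect_error(consensus_partition(er, 7), "exceeds the number of cells")
})

test_that("on separated data every member and the consensus track truth", {
  pool <- make_test_pool(3, 60, n_genes = 300, separation = 4,
                         dispersion = 0.1, seed = 7)
  nm <- log_normalise(pool)
  cfg <- ensemble_config(B = 6, projection_fraction = 0.3, encode_dim = 8,
                         encoder = "pca_fallback", k = 3, seed = 3)
  er <- run_ensemble(nm, cfg)
  member_ari <- vapply(er$members, function(a) {
    mclust::adjustedRandIndex(a, pool$labels)
  }, 1)
  expect_true(all(member_ari >= 0.9))
  cons_ari <- mclust::adjustedRandIndex(consensus_partition(er, 3),
                                        pool$labels)
  expect_gte(cons_ari, max(member_ari) - 0.05)
})

test_that("ensemble preconditions are enforced", {
  nm <- log_normalise(make_test_pool(2, 5, n_genes = 40))
  cfg <- fast_config(k = 11)
  expect_error(run_ensemble(nm, cfg), "exceeds the number of cells")
})
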