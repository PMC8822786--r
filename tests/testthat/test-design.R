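make_labelled_pool <- function(type_sizes) {
  n <- sum(type_sizes)
  count_matrix(matrix(1L, nrow = 5, ncol = n),
               sprintf("g%d", 1:5), sprintf("c%d", seq_len(n)),
               labels = rep(names(type_sizes), type_sizes))
}

test_that("pool filter threshold is exclusive at 300", {
  pool <- make_labelled_pool(c(A = 301, B = 300, C = 500))
  kept <- filter_pool(pool)
  expect_setequal(unique(kept$labels), c("A", "C"))
  expect_equal(ncol(kept$counts), 801)
  expect_equal(kept$gene_ids, pool$gene_ids)
})

test_that("pool filter handles the no-op and degenerate-threshold cases", {
  pool <- make_labelled_pool(c(A = 1000, B = 1000))
  expect_identical(filter_pool(pool)$cell_ids, pool$cell_ids)
  tiny <- make_labelled_pool(c(A = 3, B = 1))
  expect_setequal(unique(filter_pool(tiny, 0)$labels), c("A", "B"))
})

test_that("pool filter errors are informative", {
  unlabelled <- count_matrix(matrix(1L, 2, 2), c("g1", "g2"), c("c1", "c2"))
  expect_error(filter_pool(unlabelled), "labels")
  pool <- make_labelled_pool(c(A = 10))
  expect_error(filter_pool(pool, 300), "more than 300 cells")
})

test_that("design enumeration reproduces the four dataset counts", {
  expect_equal(nrow(enumerate_design("type_sweep")), 160)
  expect_equal(nrow(enumerate_design("cell_sweep")), 200)
  expect_equal(nrow(enumerate_design("imbalance")), 60)
  expect_equal(nrow(enumerate_design("large_n")), 80)
})

test_that("enumerations respect the per-setting structure", {
  ts <- enumerate_design("type_sweep")
  expect_setequal(unique(ts$n_types), 5:20)
  expect_true(all(ts$cells_per_major_type == 200))
  expect_true(all(is.na(ts$cells_per_minor_type)))

  cs <- enumerate_design("cell_sweep")
  expect_setequal(unique(cs$n_types), c(5, 10, 15, 20))
  expect_setequal(unique(cs$cells_per_major_type), seq(50, 250, 50))

  im <- enumerate_design("imbalance")
  expect_setequal(unique(im$n_types), c(10, 20))
  expect_setequal(unique(im$cells_per_minor_type), c(100, 50, 20))

  ln <- enumerate_design("large_n")
  expect_setequal(unique(ln$source), c("pool_a", "pool_b"))
  expect_setequal(unique(ln$cells_per_major_type), c(500, 1000))
  expect_true(all(table(ts$replicate) == 16))
})

test_that("enumeration seeds are deterministic and distinct", {
  a <- enumerate_design("imbalance", base_seed = 9)
  b <- enumerate_design("imbalance", base_seed = 9)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$seed), 0)
  c <- enumerate_design("imbalance", base_seed = 10)
  expect_false(identical(a$seed, c$seed))
})

test_that("unknown settings are rejected with the valid list", {
  expect_error(enumerate_design("bogus"), "type_sweep.*cell_sweep")
})

test_that("balanced sampling returns the exact per-type composition", {
  pool <- make_labelled_pool(c(A = 300, B = 300, C = 300, D = 300, E = 300))
  ds <- sample_dataset(pool, list(n_types = 5, cells_per_major_type = 200,
                                  cells_per_minor_type = NA, seed = 1))
  expect_equal(ncol(ds$data$counts), 1000)
  expect_true(all(table(ds$data$labels) == 200))
  expect_equal(ds$true_k, 5)
  expect_equal(anyDuplicated(ds$data$cell_ids), 0)
})

test_that("imbalanced sampling splits major and minor types evenly", {
  pool <- make_labelled_pool(stats::setNames(rep(250, 12),
                                             paste0("T", 1:12)))
  ds <- sample_dataset(pool, list(n_types = 10, cells_per_major_type = 200,
                                  cells_per_minor_type = 20, seed = 4))
  sizes <- table(ds$data$labels)
  expect_equal(ncol(ds$data$counts), 1100)
  expect_equal(sum(sizes == 200), 5)
  expect_equal(sum(sizes == 20), 5)
})

test_that("sampling deficits are reported with the offending type", {
  pool <- make_labelled_pool(c(A = 300, B = 300))
  expect_error(
    sample_dataset(pool, list(n_types = 2, cells_per_major_type = 400,
                              cells_per_minor_type = NA, seed = 1)),
    "has 300 cells but 400 were requested")
  expect_error(
    sample_dataset(pool, list(n_types = 5, cells_per_major_type = 10,
                              cells_per_minor_type = NA, seed = 1)),
    "2 cell types but the configuration needs 5")
})

test_that("sampling is reproducible by seed and varies across replicates", {
  pool <- make_labelled_pool(stats::setNames(rep(400, 8), paste0("T", 1:8)))
  cfgs <- enumerate_design("type_sweep")
  cfg <- as.list(cfgs[cfgs$n_types == 5 & cfgs$replicate == 1, ][1, ])
  a <- sample_dataset(pool, cfg)
  b <- sample_dataset(pool, cfg)
  expect_identical(a$data$cell_ids, b$data$cell_ids)

  reps <- cfgs[cfgs$n_types == 5, ]
  drawn <- lapply(seq_len(nrow(reps)), function(i) {
    sort(sample_dataset(pool, as.list(reps[i, ]))$data$cell_ids)
  })
  expect_equal(length(unique(drawn)), 10)
})
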