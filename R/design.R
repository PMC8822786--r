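#' Restrict a labelled pool to well-represented cell types
#'
#' Benchmark datasets are subsampled from a labelled selection pool; cell
#' types with too few cells are dropped first. The threshold is exclusive:
#' a type is retained only when it has strictly more than
#' `min_cells_exclusive` cells, so a 300-cell type is excluded at the
#' default threshold while a 301-cell type is kept. The gene set is
#' unchanged.
#'
#' @param pool A labelled [count_matrix()].
#' @param min_cells_exclusive Exclusive minimum cells per type (default 300).
#' @return The filtered [count_matrix()].
#' @export
filter_pool <- function(pool, min_cells_exclusive = 300) {
  stopifnot(inherits(pool, "count_matrix"))
  if (is.null(pool$labels)) {
    stop("filter_pool: pool has no cell-type labels", call. = FALSE)
  }
  tc <- table(pool$labels)
  keep_types <- names(tc)[tc > min_cells_exclusive]
  if (length(keep_types) == 0) {
    stop("filter_pool: no cell type has more than ", min_cells_exclusive,
         " cells", call. = FALSE)
  }
  subset_cells(pool, which(pool$labels %in% keep_types))
}

design_settings <- c("type_sweep", "cell_sweep", "imbalance", "large_n")

#' Enumerate the benchmark sampling design
#'
#' Expands one of the four benchmark settings into every dataset
#' configuration, crossed with replicates 1..10, each with a deterministic
#' derived seed:
#'
#' * `type_sweep`: 5-20 cell types, 200 cells each — 160 configurations.
#' * `cell_sweep`: 5/10/15/20 types x 50-250 cells (step 50) — 200.
#' * `imbalance`: 10 or 20 types, major types at 200 cells, minor types at
#'   100/50/20 (imbalance ratios 2:1, 4:1, 10:1) — 60.
#' * `large_n`: 5 or 10 types x 500 or 1000 cells x two source pools — 80.
#'
#' @param setting One of `"type_sweep"`, `"cell_sweep"`, `"imbalance"`,
#'   `"large_n"`.
#' @param base_seed Integer; all per-dataset seeds are derived from it.
#' @param n_replicates Replicates per configuration (default 10).
#' @return A tibble with one row per dataset configuration: columns
#'   `setting`, `n_types`, `cells_per_major_type`, `cells_per_minor_type`
#'   (NA outside the imbalance setting), `source` (NA outside `large_n`),
#'   `replicate`, `seed`.
#' @examples
#' nrow(enumerate_design("type_sweep"))  # 160
#' @export
enumerate_design <- function(setting, base_seed = 0L, n_replicates = 10L) {
  if (!is.character(setting) || length(setting) != 1 ||
      !setting %in% design_settings) {
    stop("enumerate_design: unknown setting ", deparse(setting),
         "; valid settings: ", paste(design_settings, collapse = ", "),
         call. = FALSE)
  }
  grid <- switch(
    setting,
    type_sweep = tidyr::expand_grid(
      n_types = 5:20, cells_per_major_type = 200L,
      cells_per_minor_type = NA_integer_, source = NA_character_),
    cell_sweep = tidyr::expand_grid(
      n_types = c(5L, 10L, 15L, 20L),
      cells_per_major_type = seq(50L, 250L, by = 50L),
      cells_per_minor_type = NA_integer_, source = NA_character_),
    imbalance = tidyr::expand_grid(
      n_types = c(10L, 20L), cells_per_major_type = 200L,
      cells_per_minor_type = c(100L, 50L, 20L), source = NA_character_),
    large_n = tidyr::expand_grid(
      n_types = c(5L, 10L), cells_per_major_type = c(500L, 1000L),
      cells_per_minor_type = NA_integer_,
      source = c("pool_a", "pool_b"))
  )
  setting_name <- setting  # avoid data-mask capture inside the seed lambda
  tidyr::expand_grid(grid, replicate = seq_len(n_replicates)) |>
    dplyr::mutate(
      setting = setting_name,
      seed = purrr::pmap_int(
        list(.data$n_types, .data$cells_per_major_type,
             .data$cells_per_minor_type, .data$source, .data$replicate),
        function(nt, major, minor, src, rep) {
          derive_seed(base_seed, setting_name, nt, major,
                      if (is.na(minor)) 0L else minor,
                      if (is.na(src)) "" else src, rep)
        }),
      .before = 1) |>
    dplyr::relocate("setting", "n_types", "cells_per_major_type",
                    "cells_per_minor_type", "source", "replicate", "seed")
}

#' Subsample one benchmark dataset from a labelled pool
#'
#' Selects `n_types` cell types uniformly without replacement, then samples
#' the configured number of cells per type without replacement, preserving
#' raw counts. In the imbalance setting the first half of the sampled types
#' (in sampled order) are the major types at `cells_per_major_type` cells
#' and the second half are minor types at `cells_per_minor_type` cells.
#'
#' @param pool A labelled (ideally [filter_pool()]-ed) [count_matrix()].
#' @param config A single design configuration: one row of
#'   [enumerate_design()] output (or a named list with the same fields).
#' @return A list of class `sampled_dataset`: `config`, `data` (a labelled
#'   [count_matrix()]) and `true_k`.
#' @export
sample_dataset <- function(pool, config) {
  stopifnot(inherits(pool, "count_matrix"))
  if (is.null(pool$labels)) {
    stop("sample_dataset: pool has no cell-type labels", call. = FALSE)
  }
  config <- as.list(config)
  n_types <- as.integer(config$n_types)
  available <- table(pool$labels)
  if (length(available) < n_types) {
    stop("sample_dataset: pool has ", length(available),
         " cell types but the configuration needs ", n_types, call. = FALSE)
  }
  imbalanced <- !is.null(config$cells_per_minor_type) &&
    !is.na(config$cells_per_minor_type)
  withr::with_seed(config$seed, {
    types <- sample(names(available), n_types)
    per_type <- rep(as.integer(config$cells_per_major_type), n_types)
    if (imbalanced) {
      # first half of the sampled order are major types, second half minor
      minor_idx <- seq(n_types %/% 2 + 1L, n_types)
      per_type[minor_idx] <- as.integer(config$cells_per_minor_type)
    }
    deficit <- per_type > available[types]
    if (any(deficit)) {
      d <- which(deficit)[1]
      stop("sample_dataset: type '", types[d], "' has ",
           available[types[d]], " cells but ", per_type[d],
           " were requested", call. = FALSE)
    }
    idx <- unlist(lapply(seq_len(n_types), function(i) {
      sample(which(pool$labels == types[i]), per_type[i])
    }))
  })
  structure(
    list(config = config, data = subset_cells(pool, idx), true_k = n_types),
    class = "sampled_dataset"
  )
}

#' @export
print.sampled_dataset <- function(x, ...) {
  cat("<sampled_dataset> setting=", x$config$setting %||% "custom",
      ", true_k=", x$true_k, ", ", ncol(x$data$counts), " cells\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
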