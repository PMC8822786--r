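#' Run the full benchmark over one design setting
#'
#' Ties the pieces together: filters the pool, enumerates (or accepts) the
#' design, subsamples every dataset, log-normalises it, runs the stability
#' estimator, and evaluates the consensus partition against the true
#' labels. Failures are isolated per dataset: a failing dataset is recorded
#' with its error message and the run continues.
#'
#' @param pool A labelled [count_matrix()] (or a [sim_pool_spec()], which is
#'   simulated first). For the `large_n` setting with two sources, pass a
#'   named list of two pools matching the `source` values of the design
#'   (`pool_a`, `pool_b`).
#' @param setting A design setting name (see [enumerate_design()]); ignored
#'   when `configs` is given.
#' @param configs Optional tibble of design configurations (rows as in
#'   [enumerate_design()] output) to run instead of the full enumeration —
#'   the full settings are hundreds of datasets.
#' @param est_config An [ensemble_config()] used for every dataset (its seed
#'   is re-derived per dataset).
#' @param k_grid Candidate k grid passed to [estimate_k()].
#' @param aggregate Stability aggregate (`"median"` or `"mean"`).
#' @param min_cells_exclusive Pool filter threshold (see [filter_pool()]).
#' @param base_seed Base seed for the enumeration when `configs` is NULL.
#' @param out_dir Optional directory: per-dataset JSON results and a
#'   `summary.csv` are written there.
#' @return An object of class `run_manifest`: `results` (one tibble row per
#'   dataset: config fields, `true_k`, `k_hat`, concordance scores,
#'   deviation, `failed`, `error`), `configs`, `settings` snapshot,
#'   `version`, `started`, `finished`.
#' @export
run_benchmark <- function(pool, setting = NULL, configs = NULL,
                          est_config = ensemble_config(),
                          k_grid = 2:25,
                          aggregate = c("median", "mean"),
                          min_cells_exclusive = 300,
                          base_seed = 0L,
                          out_dir = NULL) {
  aggregate <- match.arg(aggregate)
  started <- Sys.time()
  if (is.null(configs)) {
    if (is.null(setting)) {
      stop("run_benchmark: give either a setting or a configs tibble",
           call. = FALSE)
    }
    configs <- enumerate_design(setting, base_seed = base_seed)
  }
  configs <- tibble::as_tibble(configs)

  pools <- prepare_pools(pool, configs, min_cells_exclusive)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  rows <- purrr::pmap(
    list(seq_len(nrow(configs))),
    function(i) {
      cfg_row <- configs[i, ]
      res <- tryCatch({
        src <- cfg_row$source
        p <- if (!is.null(src) && !is.na(src) && src %in% names(pools)) {
          pools[[src]]
        } else {
          pools[[1]]
        }
        ds <- sample_dataset(p, cfg_row)
        nm <- log_normalise(ds$data)
        ec <- est_config
        ec$seed <- derive_seed(est_config$seed, "dataset", cfg_row$seed)
        est <- estimate_k(nm, ec, k_grid = k_grid, aggregate = aggregate)
        sc <- concordance_scores(ds$data$labels, est$consensus)
        dplyr::bind_cols(
          cfg_row,
          tibble::tibble(true_k = ds$true_k, k_hat = est$k_hat,
                         deviation = est$k_hat - ds$true_k,
                         relative_deviation =
                           (est$k_hat - ds$true_k) / ds$true_k),
          sc,
          tibble::tibble(failed = FALSE, error = NA_character_))
      }, error = function(e) {
        dplyr::bind_cols(
          cfg_row,
          tibble::tibble(true_k = NA_integer_, k_hat = NA_integer_,
                         deviation = NA_real_, relative_deviation = NA_real_,
                         ari = NA_real_, nmi = NA_real_, fm = NA_real_,
                         jaccard = NA_real_,
                         failed = TRUE, error = conditionMessage(e)))
      })
      if (!is.null(out_dir)) {
        jsonlite::write_json(
          as.list(res), file.path(out_dir, sprintf("dataset_%04d.json", i)),
          auto_unbox = TRUE, digits = NA, na = "null")
      }
      res
    })
  results <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    readr::write_csv(results, file.path(out_dir, "summary.csv"))
  }
  structure(
    list(results = results,
         configs = configs,
         settings = list(k_grid = range(k_grid), aggregate = aggregate,
                         B = est_config$B, encoder = est_config$encoder,
                         min_cells_exclusive = min_cells_exclusive,
                         base_seed = base_seed),
         version = as.character(utils::packageVersion("scstab")),
         started = started,
         finished = Sys.time()),
    class = "run_manifest"
  )
}

prepare_pools <- function(pool, configs, min_cells_exclusive) {
  as_pool <- function(p) {
    if (inherits(p, "sim_pool_spec")) p <- simulate_pool(p)
    stopifnot(inherits(p, "count_matrix"))
    filter_pool(p, min_cells_exclusive)
  }
  if (inherits(pool, "count_matrix") || inherits(pool, "sim_pool_spec")) {
    return(list(pool = as_pool(pool)))
  }
  if (is.list(pool)) {
    return(lapply(pool, as_pool))
  }
  stop("run_benchmark: pool must be a count_matrix, sim_pool_spec, ",
       "or a named list of them", call. = FALSE)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", nrow(x$results), " datasets (",
      sum(x$results$failed), " failed), scstab ", x$version, "\n", sep = "")
  invisible(x)
}

#' Tidy a benchmark manifest into its per-dataset results
#'
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @return The per-dataset results tibble.
#' @method tidy run_manifest
#' @export
tidy.run_manifest <- function(x, ...) x$results

#' One-row summary of a benchmark run
#'
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @return A one-row tibble with dataset counts, mean |relative deviation|
#'   and mean ARI over successful datasets.
#' @method glance run_manifest
#' @export
glance.run_manifest <- function(x, ...) {
  ok <- dplyr::filter(x$results, !.data$failed)
  tibble::tibble(
    n_datasets = nrow(x$results),
    n_failed = sum(x$results$failed),
    mean_abs_relative_deviation =
      if (nrow(ok)) mean(abs(ok$relative_deviation)) else NA_real_,
    mean_ari = if (nrow(ok)) mean(ok$ari) else NA_real_)
}
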