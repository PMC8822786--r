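#' Specify a synthetic labelled cell pool
#'
#' Describes a negative-binomial simulation of a labelled scRNA-seq pool:
#' `n_types` cell types with distinct marker-gene programs on a shared
#' background, overdispersed counts, and log-normal library-size variation.
#' The pool stands in for a large annotated atlas from which benchmark
#' datasets are subsampled.
#'
#' Marker genes are disjoint across types. A marker gene of type `t` has its
#' mean elevated by a factor of `2^separation` over `base_expression_rate`,
#' but only in cells of type `t`; everywhere else it behaves like a
#' background gene. Counts are negative binomial with
#' `variance = mu + dispersion * mu^2`.
#'
#' @param n_types Number of cell types (positive integer).
#' @param cells_per_type Integer vector of cells per type, length `n_types`
#'   (a single value is recycled).
#' @param n_genes Total number of genes.
#' @param n_marker_genes_per_type Marker genes per type;
#'   `n_marker_genes_per_type * n_types` must not exceed `n_genes`.
#' @param separation Log2 fold-change of marker genes over background
#'   (non-negative; 0 means no signal).
#' @param dispersion Negative-binomial overdispersion (positive).
#' @param base_expression_rate Mean count of background genes (positive).
#' @param libsize_cv Coefficient of variation of per-cell library-size
#'   factors (non-negative; 0 disables library-size variation).
#' @param seed Integer seed; simulation is fully reproducible given the spec.
#' @return An object of class `sim_pool_spec`.
#' @seealso [simulate_pool()]
#' @export
sim_pool_spec <- function(n_types,
                          cells_per_type,
                          n_genes = 2000,
                          n_marker_genes_per_type = 20,
                          separation = 3,
                          dispersion = 0.3,
                          base_expression_rate = 2,
                          libsize_cv = 0.2,
                          seed = 1L) {
  if (length(cells_per_type) == 1L) {
    cells_per_type <- rep(cells_per_type, n_types)
  }
  spec <- structure(
    list(n_types = as.integer(n_types),
         cells_per_type = as.integer(cells_per_type),
         n_genes = as.integer(n_genes),
         n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
         separation = as.numeric(separation),
         dispersion = as.numeric(dispersion),
         base_expression_rate = as.numeric(base_expression_rate),
         libsize_cv = as.numeric(libsize_cv),
         seed = as.integer(seed)),
    class = "sim_pool_spec"
  )
  validate_sim_pool_spec(spec)
  spec
}

validate_sim_pool_spec <- function(spec) {
  with(spec, {
    if (n_types < 1L) {
      stop("sim_pool_spec: n_types must be a positive integer", call. = FALSE)
    }
    if (length(cells_per_type) != n_types) {
      stop("sim_pool_spec: length(cells_per_type) [", length(cells_per_type),
           "] must equal n_types [", n_types, "]", call. = FALSE)
    }
    if (any(cells_per_type < 1L)) {
      stop("sim_pool_spec: cells_per_type must be positive", call. = FALSE)
    }
    if (n_genes < 1L) {
      stop("sim_pool_spec: n_genes must be positive", call. = FALSE)
    }
    if (n_marker_genes_per_type < 0L) {
      stop("sim_pool_spec: n_marker_genes_per_type must be non-negative",
           call. = FALSE)
    }
    if (n_marker_genes_per_type * n_types > n_genes) {
      stop("sim_pool_spec: n_marker_genes_per_type * n_types [",
           n_marker_genes_per_type * n_types, "] exceeds n_genes [", n_genes,
           "]", call. = FALSE)
    }
    if (separation < 0) {
      stop("sim_pool_spec: separation must be non-negative", call. = FALSE)
    }
    if (dispersion <= 0) {
      stop("sim_pool_spec: dispersion must be positive", call. = FALSE)
    }
    if (base_expression_rate <= 0) {
      stop("sim_pool_spec: base_expression_rate must be positive",
           call. = FALSE)
    }
    if (libsize_cv < 0) {
      stop("sim_pool_spec: libsize_cv must be non-negative", call. = FALSE)
    }
  })
  invisible(spec)
}

#' Simulate a labelled cell pool
#'
#' Draws a genes x cells raw count matrix under the model described in
#' [sim_pool_spec()]. Cell types are named `type01`, `type02`, ...; marker
#' gene identifiers carry their type (`marker_type01_...`) so simulations are
#' self-describing.
#'
#' @param spec A [sim_pool_spec()].
#' @return A labelled [count_matrix()] with `sum(cells_per_type)` cells.
#' @examples
#' pool <- simulate_pool(sim_pool_spec(3, 100, n_genes = 500, seed = 1))
#' type_counts(pool)
#' @export
simulate_pool <- function(spec) {
  validate_sim_pool_spec(spec)
  n_cells <- sum(spec$cells_per_type)
  type_names <- sprintf("type%02d", seq_len(spec$n_types))
  labels <- rep(type_names, spec$cells_per_type)

  n_marker_total <- spec$n_marker_genes_per_type * spec$n_types
  gene_ids <- character(spec$n_genes)
  if (n_marker_total > 0) {
    gene_ids[seq_len(n_marker_total)] <- sprintf(
      "marker_%s_%03d",
      rep(type_names, each = spec$n_marker_genes_per_type),
      rep(seq_len(spec$n_marker_genes_per_type), spec$n_types))
  }
  bg_idx <- setdiff(seq_len(spec$n_genes), seq_len(n_marker_total))
  gene_ids[bg_idx] <- sprintf("background_%05d", seq_along(bg_idx))

  withr::with_seed(spec$seed, {
    # per-cell library-size factor: log-normal with mean 1, CV = libsize_cv
    if (spec$libsize_cv > 0) {
      sdlog <- sqrt(log1p(spec$libsize_cv^2))
      sf <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      sf <- rep(1, n_cells)
    }

    # per-gene, per-type mean: background everywhere, elevated for own markers
    base <- spec$base_expression_rate
    fold <- 2^spec$separation
    counts <- matrix(0L, nrow = spec$n_genes, ncol = n_cells)
    size <- 1 / spec$dispersion
    for (t in seq_len(spec$n_types)) {
      cells_t <- which(labels == type_names[t])
      mu_g <- rep(base, spec$n_genes)
      if (spec$n_marker_genes_per_type > 0) {
        marker_t <- (t - 1L) * spec$n_marker_genes_per_type +
          seq_len(spec$n_marker_genes_per_type)
        mu_g[marker_t] <- base * fold
      }
      mu <- outer(mu_g, sf[cells_t])
      counts[, cells_t] <- stats::rnbinom(length(mu), size = size, mu = mu)
    }
  })

  count_matrix(counts, gene_ids,
               sprintf("cell%05d", seq_len(n_cells)), labels = labels)
}
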