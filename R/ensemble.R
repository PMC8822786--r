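#' Configure the clustering ensemble
#'
#' An ensemble member is one pass of: random gene-subspace projection ->
#' low-dimensional encoding -> clustering into `k` groups. Stability of the
#' `B` members' partitions is what the k-estimator scores.
#'
#' @param B Ensemble size (default 20; at least 2, since stability is a
#'   pairwise score).
#' @param projection_fraction Fraction of genes kept per random projection,
#'   in (0, 1]; a floor of `2 * encode_dim` genes is applied so the encoder
#'   always has room to compress.
#' @param encode_dim Dimensionality of the encoding (default 16).
#' @param encoder `"autoencoder"` (single-bottleneck network trained by
#'   reconstruction, the reference mechanism) or `"pca_fallback"` (truncated
#'   principal components; deterministic and fast, same interface).
#' @param encoder_epochs Training epochs for the autoencoder (default 30).
#' @param base_clusterer `"kmeans"` or `"plugin"`; a plugin supplies
#'   `clusterer_fun(encoding, k, seed)` returning one cluster id per cell.
#' @param clusterer_fun Plugin clustering function (see above).
#' @param k Number of clusters each member produces (>= 2).
#' @param seed Integer seed; member seeds are derived from it.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(B = 20L,
                            projection_fraction = 0.1,
                            encode_dim = 16L,
                            encoder = c("autoencoder", "pca_fallback"),
                            encoder_epochs = 30L,
                            base_clusterer = c("kmeans", "plugin"),
                            clusterer_fun = NULL,
                            k = 2L,
                            seed = 1L) {
  encoder <- match.arg(encoder)
  base_clusterer <- match.arg(base_clusterer)
  if (B < 2L) {
    stop("ensemble_config: B must be at least 2 (pairwise stability)",
         call. = FALSE)
  }
  if (projection_fraction <= 0 || projection_fraction > 1) {
    stop("ensemble_config: projection_fraction must be in (0, 1]",
         call. = FALSE)
  }
  if (k < 2L) {
    stop("ensemble_config: k must be at least 2", call. = FALSE)
  }
  if (base_clusterer == "plugin" && !is.function(clusterer_fun)) {
    stop("ensemble_config: base_clusterer = 'plugin' requires clusterer_fun",
         call. = FALSE)
  }
  structure(
    list(B = as.integer(B), projection_fraction = projection_fraction,
         encode_dim = as.integer(encode_dim), encoder = encoder,
         encoder_epochs = as.integer(encoder_epochs),
         base_clusterer = base_clusterer, clusterer_fun = clusterer_fun,
         k = as.integer(k), seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Random gene-subspace projection
#'
#' Restricts a normalised matrix to `ceiling(fraction * n_genes)` genes
#' sampled uniformly without replacement (with a floor of
#' `2 * encode_dim` genes when `encode_dim` is given). Different member
#' seeds give different gene subsets.
#'
#' @param nm A `normalized_matrix` (see [log_normalise()]).
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @param member_seed Integer seed for this member's draw.
#' @param encode_dim Optional encoding dimension used for the gene floor and
#'   feasibility check.
#' @return A `normalized_matrix` restricted to the sampled genes.
#' @export
random_projection <- function(nm, fraction, member_seed, encode_dim = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (fraction <= 0 || fraction > 1) {
    stop("random_projection: fraction must be in (0, 1]", call. = FALSE)
  }
  G <- nrow(nm$values)
  p <- ceiling(fraction * G)
  if (!is.null(encode_dim)) {
    p <- max(p, min(G, 2L * encode_dim))
    if (p <= encode_dim) {
      stop("random_projection: projection keeps ", p,
           " genes, not more than encode_dim = ", encode_dim, call. = FALSE)
    }
  }
  idx <- withr::with_seed(member_seed, sort(sample.int(G, p)))
  out <- nm
  out$values <- nm$values[idx, , drop = FALSE]
  out$gene_ids <- nm$gene_ids[idx]
  out
}

#' Encode cells into a low-dimensional space
#'
#' Reduces a (projected) normalised matrix to `encode_dim` dimensions per
#' cell. The `"autoencoder"` mode trains a single-hidden-bottleneck network
#' (tanh encoder, linear decoder, mean-squared reconstruction loss, Adam)
#' and returns the bottleneck activations; `"pca_fallback"` returns the
#' leading principal-component scores. Both are deterministic given
#' `member_seed`.
#'
#' @inheritParams random_projection
#' @param encode_dim Encoding dimensionality (must be < number of genes).
#' @param epochs Autoencoder training epochs.
#' @param encoder `"autoencoder"` or `"pca_fallback"`.
#' @return A cells x `encode_dim` numeric matrix. In `"pca_fallback"` mode
#'   the attributes `rotation` and `center` allow exact reconstruction of
#'   low-rank inputs.
#' @export
encode_cells <- function(nm, encode_dim, epochs = 30L, member_seed = 1L,
                         encoder = c("autoencoder", "pca_fallback")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  encoder <- match.arg(encoder)
  if (encode_dim >= nrow(nm$values)) {
    stop("encode_cells: encode_dim [", encode_dim,
         "] must be smaller than the number of genes [", nrow(nm$values),
         "]", call. = FALSE)
  }
  X <- t(nm$values)  # cells x genes
  if (!all(is.finite(X))) {
    stop("encode_cells: input contains non-finite values", call. = FALSE)
  }
  if (encoder == "pca_fallback") {
    pc <- stats::prcomp(X, rank. = encode_dim, center = TRUE, scale. = FALSE)
    E <- pc$x[, seq_len(encode_dim), drop = FALSE]
    attr(E, "rotation") <- pc$rotation[, seq_len(encode_dim), drop = FALSE]
    attr(E, "center") <- pc$center
    rownames(E) <- nm$cell_ids
    return(E)
  }
  E <- train_autoencoder(X, encode_dim, epochs, member_seed)
  rownames(E) <- nm$cell_ids
  E
}

# Single-bottleneck autoencoder in plain R:
#   h = tanh(X W1 + b1),  Xhat = h W2 + b2,  loss = mean((X - Xhat)^2)
# trained with minibatch Adam. Input columns are standardised first so the
# learning rate is scale-free. Deterministic given `seed`.
train_autoencoder <- function(X, d, epochs, seed,
                              lr = 0.01, batch_size = 32L) {
  n <- nrow(X); G <- ncol(X)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  withr::with_seed(seed, {
    W1 <- matrix(stats::rnorm(G * d, sd = sqrt(1 / G)), G, d)
    b1 <- rep(0, d)
    W2 <- matrix(stats::rnorm(d * G, sd = sqrt(1 / d)), d, G)
    b2 <- rep(0, G)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        nb <- nrow(Xb)

        A1 <- sweep(Xb %*% params$W1, 2, params$b1, `+`)
        H <- tanh(A1)
        Xhat <- sweep(H %*% params$W2, 2, params$b2, `+`)
        err <- Xhat - Xb                         # nb x G
        gXhat <- 2 * err / (nb * G)
        grads <- list(
          W1 = crossprod(Xb, (gXhat %*% t(params$W2)) * (1 - H^2)),
          b1 = colSums((gXhat %*% t(params$W2)) * (1 - H^2)),
          W2 = crossprod(H, gXhat),
          b2 = colSums(gXhat))

        t <- t + 1
        for (nm_ in names(params)) {
          m[[nm_]] <- beta1 * m[[nm_]] + (1 - beta1) * grads[[nm_]]
          v[[nm_]] <- beta2 * v[[nm_]] + (1 - beta2) * grads[[nm_]]^2
          mhat <- m[[nm_]] / (1 - beta1^t)
          vhat <- v[[nm_]] / (1 - beta2^t)
          params[[nm_]] <- params[[nm_]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
  })
  tanh(sweep(Xs %*% params$W1, 2, params$b1, `+`))
}

# Cluster one encoding into exactly k groups.
cluster_encoding <- function(E, k, seed, cfg) {
  if (k > nrow(E)) {
    stop("cluster_encoding: k [", k, "] exceeds the number of cells [",
         nrow(E), "]", call. = FALSE)
  }
  if (cfg$base_clusterer == "plugin") {
    return(as.integer(factor(cfg$clusterer_fun(E, k, seed))))
  }
  withr::with_seed(seed, {
    km <- stats::kmeans(E, centers = k, nstart = 10L, iter.max = 100L)
  })
  as.integer(km$cluster)
}

# Build the B per-member encodings; reused across k during estimation.
# `salt` distinguishes per-k re-encoding (reuse_encodings = FALSE) from the
# shared-encoding path (salt = 0).
build_encodings <- function(nm, cfg, salt = 0L) {
  lapply(seq_len(cfg$B), function(b) {
    ms <- derive_seed(cfg$seed, "member", b, salt)
    proj <- random_projection(nm, cfg$projection_fraction, ms,
                              encode_dim = cfg$encode_dim)
    encode_cells(proj, cfg$encode_dim, cfg$encoder_epochs, ms,
                 encoder = cfg$encoder)
  })
}

#' Run the clustering ensemble at one k
#'
#' For each of the `B` members: project the genes, encode the cells, and
#' cluster the encoding into `cfg$k` groups. Returns all member partitions
#' and the co-association matrix (fraction of members placing each pair of
#' cells in the same cluster).
#'
#' @param nm A `normalized_matrix`.
#' @param cfg An [ensemble_config()].
#' @param encodings Optional precomputed [build_encodings()] output, so the
#'   same projections/encodings can be reused across different k.
#' @return An object of class `ensemble_result`: `members` (list of integer
#'   partitions), `coassociation` (cells x cells), `config`.
#' @export
run_ensemble <- function(nm, cfg, encodings = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(cfg, "ensemble_config"))
  n <- ncol(nm$values)
  if (cfg$k > n) {
    stop("run_ensemble: k [", cfg$k, "] exceeds the number of cells [", n,
         "]", call. = FALSE)
  }
  if (is.null(encodings)) encodings <- build_encodings(nm, cfg, salt = cfg$k)
  members <- lapply(seq_len(cfg$B), function(b) {
    tryCatch(
      cluster_encoding(encodings[[b]], cfg$k,
                       derive_seed(cfg$seed, "cluster", b, cfg$k), cfg),
      error = function(e) {
        stop("run_ensemble: base clusterer failed on member ", b, ": ",
             conditionMessage(e), call. = FALSE)
      })
  })
  co <- matrix(0, n, n)
  for (a in members) {
    co <- co + (outer(a, a, `==`) * 1)
  }
  co <- co / length(members)
  dimnames(co) <- list(nm$cell_ids, nm$cell_ids)
  structure(
    list(members = members, coassociation = co, config = cfg,
         cell_ids = nm$cell_ids),
    class = "ensemble_result"
  )
}

#' Consensus partition from an ensemble
#'
#' Average-linkage hierarchical clustering of the co-association
#' dissimilarity (1 - co-association), cut into `k` clusters.
#'
#' @param er An [run_ensemble()] result.
#' @param k Number of consensus clusters.
#' @return Integer vector of cluster ids, one per cell.
#' @export
consensus_partition <- function(er, k) {
  stopifnot(inherits(er, "ensemble_result"))
  n <- nrow(er$coassociation)
  if (k > n) {
    stop("consensus_partition: k [", k, "] exceeds the number of cells [",
         n, "]", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - er$coassociation),
                      method = "average")
  unname(stats::cutree(hc, k = k))
}

#' Plot a co-association matrix
#'
#' Heatmap of the fraction of ensemble members co-clustering each cell pair,
#' with cells ordered by the consensus dendrogram.
#'
#' @param er An [run_ensemble()] result.
#' @return A ggplot object.
#' @export
plot_coassociation <- function(er) {
  stopifnot(inherits(er, "ensemble_result"))
  ord <- stats::hclust(stats::as.dist(1 - er$coassociation),
                       method = "average")$order
  df <- tibble::as_tibble(er$coassociation[ord, ord], .name_repair = "minimal")
  names(df) <- paste0("c", seq_along(ord))
  df$row <- seq_along(ord)
  df <- tidyr::pivot_longer(df, -"row", names_to = "col",
                            values_to = "coassociation")
  df$col <- as.integer(sub("^c", "", df$col))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$coassociation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-assoc.") +
    ggplot2::theme_minimal()
}
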