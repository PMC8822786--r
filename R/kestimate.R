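#' Stability of a set of member partitions
#'
#' Pairwise normalised mutual information over all `B(B-1)/2` unordered
#' pairs of member partitions, aggregated by the median (default) or mean.
#' High stability at a given k indicates that k reflects structure that
#' survives random projection and re-encoding.
#'
#' @param members List of at least two cluster assignments over the same
#'   cells.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return A single stability score in `[0, 1]`.
#' @examples
#' stability_score(list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 1, 2, 2)))
#' @export
stability_score <- function(members, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(members) < 2) {
    stop("stability_score: need at least 2 member partitions", call. = FALSE)
  }
  n <- lengths(members)
  if (length(unique(n)) != 1) {
    stop("stability_score: member partitions cover different numbers of cells",
         call. = FALSE)
  }
  pairs <- utils::combn(length(members), 2)
  scores <- apply(pairs, 2, function(ij) {
    suppressWarnings(nmi(members[[ij[1]]], members[[ij[2]]]))
  })
  if (aggregate == "median") stats::median(scores) else mean(scores)
}

#' Estimate the number of cell types from clustering stability
#'
#' Runs the projection -> encode -> cluster ensemble at every k in
#' `k_grid`, scores each k by the aggregate pairwise NMI among the B member
#' partitions, and selects the k with the highest stability (ties broken to
#' the smallest k). By default the same B encodings are reused across the
#' whole grid, so each k only re-runs the base clusterer; set
#' `reuse_encodings = FALSE` to re-project and re-encode per k.
#'
#' @param nm A `normalized_matrix` (see [log_normalise()]).
#' @param cfg An [ensemble_config()]; its `k` field is ignored in favour of
#'   the grid.
#' @param k_grid Candidate numbers of clusters (default `2:25`).
#' @param aggregate Stability aggregate, `"median"` (default) or `"mean"`.
#' @param reuse_encodings Reuse the member encodings across k (default TRUE).
#' @return An object of class `scstab_estimate`: `k_hat`, `profile`
#'   (tibble of k and stability score), `consensus` (integer partition at
#'   `k_hat`), `members` (partitions at `k_hat`), `config`, `aggregate`.
#' @export
estimate_k <- function(nm, cfg, k_grid = 2:25,
                       aggregate = c("median", "mean"),
                       reuse_encodings = TRUE) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(cfg, "ensemble_config"))
  aggregate <- match.arg(aggregate)
  k_grid <- sort(unique(as.integer(k_grid)))
  n <- ncol(nm$values)
  if (max(k_grid) > n) {
    stop("estimate_k: max(k_grid) [", max(k_grid),
         "] exceeds the number of cells [", n, "]", call. = FALSE)
  }
  encodings <- if (reuse_encodings) build_encodings(nm, cfg) else NULL
  per_k <- lapply(k_grid, function(k) {
    cfg_k <- cfg
    cfg_k$k <- k
    er <- tryCatch(
      run_ensemble(nm, cfg_k, encodings = encodings),
      error = function(e) {
        stop("estimate_k: ensemble failed at k = ", k, ": ",
             conditionMessage(e), call. = FALSE)
      })
    # keep score + member partitions only; the (cells x cells)
    # co-association matrix is rebuilt once, at the selected k
    list(score = stability_score(er$members, aggregate),
         members = er$members)
  })
  profile <- tibble::tibble(
    k = k_grid,
    score = vapply(per_k, `[[`, numeric(1), "score"))
  best <- which.max(profile$score)  # which.max takes the first (smallest k)
  cfg_best <- cfg
  cfg_best$k <- k_grid[best]
  er_best <- run_ensemble(nm, cfg_best, encodings = encodings)
  structure(
    list(k_hat = k_grid[best],
         profile = profile,
         consensus = consensus_partition(er_best, k_grid[best]),
         members = er_best$members,
         config = cfg,
         aggregate = aggregate),
    class = "scstab_estimate"
  )
}

#' @export
print.scstab_estimate <- function(x, ...) {
  cat("<scstab_estimate> k_hat =", x$k_hat,
      sprintf("(stability %.3f, %s of pairwise NMI over B = %d members)\n",
              x$profile$score[x$profile$k == x$k_hat], x$aggregate,
              x$config$B))
  cat("  grid:", min(x$profile$k), "..", max(x$profile$k), "\n")
  invisible(x)
}

#' Tidy a stability estimate into its per-k profile
#'
#' @param x A `scstab_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `k`, `score`, and `is_k_hat`.
#' @method tidy scstab_estimate
#' @export
tidy.scstab_estimate <- function(x, ...) {
  dplyr::mutate(x$profile, is_k_hat = .data$k == x$k_hat)
}

#' One-row summary of a stability estimate
#'
#' @param x A `scstab_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `k_hat`, `best_score`, `B`, `encoder`,
#'   `aggregate`, `k_min`, `k_max`.
#' @method glance scstab_estimate
#' @export
glance.scstab_estimate <- function(x, ...) {
  tibble::tibble(
    k_hat = x$k_hat,
    best_score = x$profile$score[x$profile$k == x$k_hat],
    B = x$config$B,
    encoder = x$config$encoder,
    aggregate = x$aggregate,
    k_min = min(x$profile$k),
    k_max = max(x$profile$k))
}

#' Plot a stability profile
#'
#' Stability score against candidate k, with the selected k marked.
#'
#' @param object A `scstab_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scstab_estimate
#' @export
autoplot.scstab_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_k_hat), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::geom_vline(xintercept = object$k_hat, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "candidate number of cell types (k)",
                  y = paste0("stability (", object$aggregate,
                             " pairwise NMI)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
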