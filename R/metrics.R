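#' Pair counts between two partitions
#'
#' Classifies all `N(N-1)/2` unordered cell pairs by their co-membership
#' under two partitions `U` and `V` of the same cells:
#' `n11` pairs together in both, `n00` apart in both, `n01` together in `U`
#' only, `n10` together in `V` only. Computed from the contingency table, so
#' it scales to large `N`; the counts always satisfy
#' `n11 + n00 + n01 + n10 = N(N-1)/2`.
#'
#' @param u,v Cluster assignments (vectors of equal length; any label type).
#' @return A tibble with columns `n11`, `n00`, `n01`, `n10`, `n_cells`.
#' @examples
#' pair_counts(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
pair_counts <- function(u, v) {
  if (length(u) != length(v)) {
    stop("pair_counts: partitions have different lengths (", length(u),
         " vs ", length(v), ")", call. = FALSE)
  }
  n <- length(u)
  ct <- table(u, v)
  total <- choose(n, 2)
  n11 <- sum(choose(ct, 2))
  n01 <- sum(choose(rowSums(ct), 2)) - n11  # together in U only
  n10 <- sum(choose(colSums(ct), 2)) - n11  # together in V only
  n00 <- total - n11 - n01 - n10
  tibble::tibble(n11 = n11, n00 = n00, n01 = n01, n10 = n10, n_cells = n)
}

#' Adjusted Rand index from pair counts
#'
#' `ARI = 2 (n00 n11 - n01 n10) / ((n00 + n01)(n01 + n11) +
#' (n00 + n10)(n10 + n11))`. When the denominator is zero the partitions are
#' either identical (both trivial) — returns 1 — or degenerate in opposite
#' ways — returns 0 with a warning.
#'
#' @param pc A [pair_counts()] row (tibble or named list).
#' @return ARI in `[-1, 1]`; 1 iff the partitions agree on every pair.
#' @export
ari <- function(pc) {
  num <- 2 * (pc$n00 * pc$n11 - pc$n01 * pc$n10)
  den <- (pc$n00 + pc$n01) * (pc$n01 + pc$n11) +
    (pc$n00 + pc$n10) * (pc$n10 + pc$n11)
  if (den == 0) {
    if (pc$n01 == 0 && pc$n10 == 0) return(1)
    warning("ari: degenerate pair counts with non-identical partitions; ",
            "returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Fowlkes-Mallows index from pair counts
#'
#' `FM = sqrt((n11 / (n11 + n01)) * (n11 / (n11 + n10)))`; defined as 0 when
#' `n11 = 0` and a denominator vanishes.
#'
#' @inheritParams ari
#' @return FM in `[0, 1]`.
#' @export
fm_index <- function(pc) {
  if (pc$n11 == 0 && (pc$n11 + pc$n01 == 0 || pc$n11 + pc$n10 == 0)) {
    return(0)
  }
  sqrt((pc$n11 / (pc$n11 + pc$n01)) * (pc$n11 / (pc$n11 + pc$n10)))
}

#' Jaccard index from pair counts
#'
#' `Jaccard = n11 / (n11 + n10 + n01)`; defined as 0 when all three counts
#' are 0.
#'
#' @inheritParams ari
#' @return Jaccard in `[0, 1]`.
#' @export
jaccard_index <- function(pc) {
  den <- pc$n11 + pc$n10 + pc$n01
  if (den == 0) return(0)
  pc$n11 / den
}

# Contingency-table entropies and mutual information, in bits.
entropy_stats <- function(u, v) {
  n <- length(u)
  ct <- table(u, v) / n
  pu <- rowSums(ct)
  pv <- colSums(ct)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  nz <- ct > 0
  mi <- sum(ct[nz] * log2(ct[nz] / outer(pu, pv)[nz]))
  list(I_UV = max(mi, 0), H_U = h(pu), H_V = h(pv))
}

#' Normalised mutual information between two partitions
#'
#' Mutual information and entropies are computed in bits from the
#' contingency table. The default `"standard"` normalisation,
#' `2 I(U;V) / (H(U) + H(V))`, is 1 for identical partitions. The
#' `"as_printed"` variant, `I(U;V) / (H(U) + H(V))`, halves every value
#' (0.5 for identical partitions) and is retained for comparability with
#' texts that state the formula without the factor 2.
#'
#' When either partition has a single cluster its entropy is 0: the result
#' is 1 if both partitions are trivially identical, else 0, with a warning.
#'
#' @param u,v Cluster assignments of equal length.
#' @param normalization `"standard"` (default) or `"as_printed"`.
#' @return NMI in `[0, 1]` (standard) or `[0, 0.5]` (as printed).
#' @export
nmi <- function(u, v, normalization = c("standard", "as_printed")) {
  normalization <- match.arg(normalization)
  if (length(u) != length(v)) {
    stop("nmi: partitions have different lengths", call. = FALSE)
  }
  es <- entropy_stats(u, v)
  if (es$H_U == 0 || es$H_V == 0) {
    identical_parts <- es$H_U == 0 && es$H_V == 0
    if (!identical_parts) {
      warning("nmi: a partition has a single cluster (zero entropy); ",
              "returning 0", call. = FALSE)
      return(0)
    }
    return(1)
  }
  fac <- if (normalization == "standard") 2 else 1
  fac * es$I_UV / (es$H_U + es$H_V)
}

#' All four concordance scores between two partitions
#'
#' Convenience wrapper returning ARI, NMI (standard normalisation),
#' Fowlkes-Mallows and Jaccard in one row. All four equal 1 when the
#' partitions are identical up to relabelling; all are invariant to cluster
#' relabelling and cell reordering.
#'
#' @param u,v Cluster assignments of equal length.
#' @return A one-row tibble with columns `ari`, `nmi`, `fm`, `jaccard`.
#' @examples
#' concordance_scores(c(1, 1, 1, 2, 2), c("a", "a", "b", "b", "b"))
#' @export
concordance_scores <- function(u, v) {
  pc <- pair_counts(u, v)
  tibble::tibble(
    ari = ari(pc),
    nmi = suppressWarnings(nmi(u, v)),
    fm = fm_index(pc),
    jaccard = jaccard_index(pc)
  )
}

#' Deviation statistics of k estimates against the truth
#'
#' Deviation is `estimate - true_k` (positive = over-estimation); relative
#' deviation divides by `true_k`. `sd_estimate` is the sample standard
#' deviation of the estimates over replicates (NA with a single estimate).
#'
#' @param estimates Integer vector of estimated numbers of cell types.
#' @param true_k True number of cell types (positive integer).
#' @return A list with `per_estimate` (tibble: `estimate`, `deviation`,
#'   `relative_deviation`), `mean_relative_deviation`, and `sd_estimate`.
#' @examples
#' deviation_stats(c(8, 10, 12), true_k = 10)
#' @export
deviation_stats <- function(estimates, true_k) {
  if (length(estimates) == 0) {
    stop("deviation_stats: no estimates supplied", call. = FALSE)
  }
  if (true_k < 1) {
    stop("deviation_stats: true_k must be at least 1", call. = FALSE)
  }
  dev <- estimates - true_k
  list(
    per_estimate = tibble::tibble(
      estimate = estimates,
      deviation = dev,
      relative_deviation = dev / true_k),
    mean_relative_deviation = mean(dev / true_k),
    sd_estimate = if (length(estimates) > 1) stats::sd(estimates) else NA_real_
  )
}
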