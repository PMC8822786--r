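#' Performance-rubric thresholds
#'
#' Cutoffs used to call a method good, intermediate or poor on each
#' criterion: magnitude of relative deviation of the estimated number of
#' cell types (<= 0.20 good, >= 0.50 poor), standard deviation of the
#' estimates across replicates (<= 2 / >= 5 cell types), mean clustering
#' concordance (>= 0.7 / <= 0.5; note the direction is reversed), mean
#' running time per dataset (<= 120 s / >= 360 s) and mean peak memory
#' (<= 4 Gb / >= 8 Gb). Boundary values fall in the better category.
#'
#' @return A named list of thresholds.
#' @export
criterion_thresholds <- function() {
  list(
    deviation = list(good = 0.20, poor = 0.50, higher_is_better = FALSE),
    sd = list(good = 2, poor = 5, higher_is_better = FALSE),
    concordance = list(good = 0.7, poor = 0.5, higher_is_better = TRUE),
    time_s = list(good = 120, poor = 360, higher_is_better = FALSE),
    memory_gb = list(good = 4, poor = 8, higher_is_better = FALSE)
  )
}

#' Categorise one performance measurement
#'
#' @param criterion One of `"deviation"`, `"sd"`, `"concordance"`,
#'   `"time_s"`, `"memory_gb"`. Deviation is judged on its magnitude, so a
#'   signed relative deviation may be passed directly.
#' @param value The measured value (finite).
#' @param thresholds See [criterion_thresholds()].
#' @return `"good"`, `"intermediate"` or `"poor"`.
#' @examples
#' categorize("deviation", 0.35)   # "intermediate"
#' categorize("concordance", 0.72) # "good"
#' @export
categorize <- function(criterion, value, thresholds = criterion_thresholds()) {
  if (!criterion %in% names(thresholds)) {
    stop("categorize: unknown criterion '", criterion, "'; expected one of ",
         paste(names(thresholds), collapse = ", "), call. = FALSE)
  }
  if (!is.finite(value)) {
    stop("categorize: value for '", criterion, "' must be finite",
         call. = FALSE)
  }
  th <- thresholds[[criterion]]
  if (criterion == "deviation") value <- abs(value)
  if (th$higher_is_better) {
    if (value >= th$good) return("good")
    if (value <= th$poor) return("poor")
  } else {
    if (value <= th$good) return("good")
    if (value >= th$poor) return("poor")
  }
  "intermediate"
}

#' Summarise benchmark records into a performance rubric
#'
#' Aggregates per-dataset evaluation records into the per-criterion
#' categories: mean |relative deviation|, standard deviation of the k
#' estimates (within replicate groups given by `true_k`, or a `group`
#' column when present, then averaged), and mean concordance (average of
#' the available `ari`/`nmi`/`fm`/`jaccard` columns, or a `concordance`
#' column). Running time and peak memory are accepted only as externally
#' supplied measurements; without them those criteria are marked
#' `not assessed` and excluded from the rank key.
#'
#' @param records Tibble/data frame with at least `true_k` and `k_hat`;
#'   optionally concordance columns and a `group` column.
#' @param time_s,memory_gb Optional numeric vectors of externally measured
#'   per-dataset running times (seconds) and peak memory (Gb).
#' @param thresholds See [criterion_thresholds()].
#' @return An object of class `performance_summary`: a tibble `table`
#'   (criterion, value, category) plus a rank key (`n_good`,
#'   `n_intermediate`) counting assessed criteria.
#' @export
summarise_performance <- function(records, time_s = NULL, memory_gb = NULL,
                                  thresholds = criterion_thresholds()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    stop("summarise_performance: no records supplied", call. = FALSE)
  }
  if (!all(c("true_k", "k_hat") %in% names(records))) {
    stop("summarise_performance: records need columns true_k and k_hat",
         call. = FALSE)
  }
  dev_value <- mean(abs((records$k_hat - records$true_k) / records$true_k))
  grp <- if ("group" %in% names(records)) records$group else records$true_k
  sd_value <- tibble::tibble(k_hat = records$k_hat, grp = grp) |>
    dplyr::summarise(s = stats::sd(.data$k_hat), .by = "grp") |>
    dplyr::pull("s") |>
    mean(na.rm = TRUE)

  conc_cols <- intersect(c("ari", "nmi", "fm", "jaccard", "concordance"),
                         names(records))
  conc_value <- if (length(conc_cols) > 0) {
    mean(rowMeans(records[, conc_cols, drop = FALSE]))
  } else {
    NA_real_
  }

  rows <- list(
    tibble::tibble(criterion = "deviation", value = dev_value),
    tibble::tibble(criterion = "sd", value = sd_value),
    tibble::tibble(criterion = "concordance", value = conc_value),
    tibble::tibble(criterion = "time_s",
                   value = if (is.null(time_s)) NA_real_ else mean(time_s)),
    tibble::tibble(criterion = "memory_gb",
                   value = if (is.null(memory_gb)) NA_real_
                           else mean(memory_gb))
  )
  tab <- dplyr::bind_rows(rows) |>
    dplyr::mutate(category = purrr::map2_chr(
      .data$criterion, .data$value,
      function(cr, v) {
        if (is.na(v)) "not assessed" else categorize(cr, v, thresholds)
      }))
  structure(
    list(table = tab,
         n_good = sum(tab$category == "good"),
         n_intermediate = sum(tab$category == "intermediate")),
    class = "performance_summary"
  )
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary> rank key: good =", x$n_good,
      ", intermediate =", x$n_intermediate, "\n")
  print(x$table)
  invisible(x)
}

#' Plot a performance summary as a category grid
#'
#' @param object A [summarise_performance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_summary
#' @export
autoplot.performance_summary <- function(object, ...) {
  df <- dplyr::mutate(object$table, method = "method")
  ggplot2::ggplot(df, ggplot2::aes(.data$criterion, .data$method,
                                   fill = .data$category)) +
    ggplot2::geom_tile(colour = "white", linewidth = 1) +
    ggplot2::scale_fill_manual(values = c(
      good = "#1a9850", intermediate = "#fee08b", poor = "#d73027",
      `not assessed` = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
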