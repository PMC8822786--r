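#' Construct a labelled count matrix
#'
#' The basic container used throughout the package: a sparse genes x cells
#' matrix of raw (un-normalised) integer counts, with gene and cell
#' identifiers and, optionally, one cell-type label per cell.
#'
#' @param counts A non-negative integer matrix (genes in rows, cells in
#'   columns); dense matrices are converted to sparse storage.
#' @param gene_ids Character vector of gene identifiers, one per row.
#' @param cell_ids Character vector of cell identifiers, one per column.
#' @param labels Optional character vector of cell-type labels, one per cell.
#' @return An object of class `count_matrix`.
#' @examples
#' cm <- count_matrix(matrix(0:5, nrow = 2), c("g1", "g2"),
#'                    c("c1", "c2", "c3"), labels = c("A", "A", "B"))
#' cm
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, labels = NULL) {
  counts <- counts * 1  # logical / pattern matrices become numeric
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) {
    stop("count_matrix: counts must be non-negative", call. = FALSE)
  }
  if (any(counts@x != round(counts@x))) {
    stop("count_matrix: counts must be integral", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids)) {
    stop("count_matrix: nrow(counts) [", nrow(counts), "] != length(gene_ids) [",
         length(gene_ids), "]", call. = FALSE)
  }
  if (ncol(counts) != length(cell_ids)) {
    stop("count_matrix: ncol(counts) [", ncol(counts), "] != length(cell_ids) [",
         length(cell_ids), "]", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(cell_ids)) {
      stop("count_matrix: labels must have one entry per cell (got ",
           length(labels), ", expected ", length(cell_ids), ")", call. = FALSE)
    }
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = labels),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells", sep = "")
  if (!is.null(x$labels)) {
    cat("; ", length(unique(x$labels)), " cell types", sep = "")
  }
  cat("\n  nonzero entries: ", Matrix::nnzero(x$counts),
      sprintf(" (%.1f%%)", 100 * Matrix::nnzero(x$counts) /
                prod(dim(x$counts))), "\n", sep = "")
  invisible(x)
}

#' Tabulate cells per cell type
#'
#' @param cm A `count_matrix` with labels.
#' @return A tibble with columns `label` and `n_cells`.
#' @export
type_counts <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$labels)) {
    stop("type_counts: count matrix has no cell-type labels", call. = FALSE)
  }
  tibble::tibble(label = cm$labels) |>
    dplyr::count(.data$label, name = "n_cells") |>
    dplyr::arrange(.data$label)
}

# Subset a count_matrix by cell index, keeping labels aligned.
subset_cells <- function(cm, idx) {
  count_matrix(cm$counts[, idx, drop = FALSE], cm$gene_ids,
               cm$cell_ids[idx],
               labels = if (is.null(cm$labels)) NULL else cm$labels[idx])
}
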