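#' Write a count matrix as Matrix Market plus sidecar TSVs
#'
#' Writes the standard sparse exchange layout: `matrix.mtx` (coordinate
#' format), `genes.tsv`, `barcodes.tsv` and, when labels are present,
#' `labels.tsv` (one entry per line, no header).
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory; created if missing.
#' @return `dir`, invisibly.
#' @seealso [read_counts_mtx()]
#' @export
write_counts_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(cm$labels)) {
    writeLines(cm$labels, file.path(dir, "labels.tsv"))
  }
  invisible(dir)
}

#' Read a count matrix from Matrix Market plus sidecar TSVs
#'
#' Inverse of [write_counts_mtx()]: the round trip is lossless for counts,
#' identifiers and labels.
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `labels.tsv`.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) {
    stop("read_counts_mtx: no matrix.mtx in ", dir, call. = FALSE)
  }
  counts <- tryCatch(
    Matrix::readMM(mtx_path),
    error = function(e) {
      stop("read_counts_mtx: malformed MTX file ", mtx_path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  gene_ids <- readLines(file.path(dir, "genes.tsv"))
  cell_ids <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(counts) != length(gene_ids)) {
    stop("read_counts_mtx: matrix.mtx declares ", nrow(counts),
         " genes but genes.tsv has ", length(gene_ids), " lines",
         call. = FALSE)
  }
  if (ncol(counts) != length(cell_ids)) {
    stop("read_counts_mtx: matrix.mtx declares ", ncol(counts),
         " cells but barcodes.tsv has ", length(cell_ids), " lines",
         call. = FALSE)
  }
  labels_path <- file.path(dir, "labels.tsv")
  labels <- NULL
  if (file.exists(labels_path)) {
    labels <- readLines(labels_path)
    if (length(labels) != length(cell_ids)) {
      stop("read_counts_mtx: labels.tsv has ", length(labels),
           " lines but there are ", length(cell_ids), " cells", call. = FALSE)
    }
  }
  count_matrix(as.matrix(counts), gene_ids, cell_ids, labels = labels)
}

#' Write / read a dense CSV count matrix
#'
#' Alternative plain-text layout: genes as rows, a leading `gene_id` column,
#' one column per cell (header = cell identifiers). Labels, when present, go
#' to a `<stem>_labels.tsv` next to the CSV.
#'
#' @param cm A [count_matrix()].
#' @param path CSV file path.
#' @return `path` (write) or a [count_matrix()] (read).
#' @export
write_counts_csv <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- tibble::as_tibble(as.matrix(cm$counts), .name_repair = "minimal")
  names(df) <- cm$cell_ids
  df <- dplyr::bind_cols(tibble::tibble(gene_id = cm$gene_ids), df)
  readr::write_csv(df, path)
  if (!is.null(cm$labels)) {
    writeLines(cm$labels, labels_sidecar(path))
  }
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  gene_ids <- df$gene_id
  mat <- as.matrix(df[, -1, drop = FALSE])
  labels <- NULL
  if (file.exists(labels_sidecar(path))) {
    labels <- readLines(labels_sidecar(path))
  }
  count_matrix(mat, gene_ids, colnames(mat), labels = labels)
}

labels_sidecar <- function(path) {
  paste0(sub("\\.csv$", "", path), "_labels.tsv")
}
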