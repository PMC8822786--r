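#' Log-normalise a raw count matrix
#'
#' Converts raw counts to log-normalised values using library-size size
#' factors: each cell's size factor is its library size divided by the mean
#' library size over cells with nonzero counts, and
#' `value = log_base(count / size_factor + pseudocount)`. With equal library
#' sizes this reduces to `log2(count + 1)`. Cells with zero library size
#' get all-zero columns and a warning.
#'
#' @param cm A [count_matrix()].
#' @param pseudocount Positive pseudocount added before the log (default 1).
#' @param log_base Logarithm base, 2 or `exp(1)` (default 2).
#' @return An object of class `normalized_matrix`: dense `values`
#'   (genes x cells) plus the identifiers, labels, and normalisation
#'   parameters carried through.
#' @export
log_normalise <- function(cm, pseudocount = 1, log_base = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (pseudocount <= 0) {
    stop("log_normalise: pseudocount must be positive", call. = FALSE)
  }
  libsize <- Matrix::colSums(cm$counts)
  if (all(libsize == 0)) {
    stop("log_normalise: every cell has zero counts", call. = FALSE)
  }
  nonzero <- libsize > 0
  if (any(!nonzero)) {
    warning("log_normalise: ", sum(!nonzero),
            " cell(s) with zero library size set to all-zero columns",
            call. = FALSE)
  }
  sf <- libsize / mean(libsize[nonzero])
  values <- as.matrix(cm$counts)
  values[, nonzero] <- sweep(values[, nonzero, drop = FALSE], 2, sf[nonzero],
                             `/`)
  values <- log(values + pseudocount, base = log_base)
  values[, !nonzero] <- 0
  structure(
    list(values = values, gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
         labels = cm$labels, pseudocount = pseudocount, log_base = log_base,
         size_factors = sf),
    class = "normalized_matrix"
  )
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (pseudocount=", x$pseudocount, ", base=",
      format(x$log_base), ")\n", sep = "")
  invisible(x)
}
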