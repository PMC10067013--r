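#' Read a cells-by-markers expression matrix
#'
#' Reads single-cell protein expression from an FCS 3.0/3.1 file or from a
#' delimited text file (comma-separated, header row of marker names, one row
#' per cell). Only the requested channels are kept, in the requested order;
#' file row order is preserved. No compensation or spillover correction is
#' applied (CyTOF channels have minimal spillover), and inputs are assumed
#' pre-gated.
#'
#' @param path path to the input file.
#' @param format `"fcs"` or `"delimited"`. Defaults to `"fcs"` for files
#'   ending in `.fcs` (case-insensitive), `"delimited"` otherwise.
#' @param channels optional character vector of marker names to keep.
#' @param sep field separator for delimited files.
#' @return numeric matrix (cells x markers) with `colnames` set to marker
#'   names and no row names.
#' @export
read_expression <- function(path, format = NULL, channels = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  }
  format <- match.arg(format, c("fcs", "delimited"))
  X <- if (format == "fcs") {
    read_fcs(path)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "numeric")
    as.matrix(df)
  }
  if (anyNA(X) || !all(is.finite(X)))
    stop("non-numeric or non-finite cell value in ", path, call. = FALSE)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("marker names missing or duplicated in ", path, call. = FALSE)
  if (!is.null(channels)) {
    missing <- setdiff(channels, colnames(X))
    if (length(missing))
      stop("requested channel(s) absent: ", paste(missing, collapse = ", "),
           call. = FALSE)
    X <- X[, channels, drop = FALSE]
  }
  rownames(X) <- NULL
  X
}

#' Arcsinh-transform an expression matrix
#'
#' The standard mass-cytometry variance-stabilizing transform
#' `y = asinh(x / cofactor)`, applied entrywise. The default co-factor of 5
#' is the conventional choice for CyTOF ion counts.
#'
#' @param X numeric matrix (cells x markers).
#' @param cofactor positive scale divisor; default 5.
#' @return matrix of the same shape and dimnames.
#' @export
arcsinh_transform <- function(X, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a positive scalar", call. = FALSE)
  check_matrix(X, "X")
  Y <- asinh(X / cofactor)
  dimnames(Y) <- dimnames(X)
  Y
}

#' Read a label vector from a one-column delimited file
#'
#' @param path file with a header line followed by one label per line.
#' @return character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop("empty label file", call. = FALSE)
  df[[1L]]
}

#' Write a score or rank table to a delimited file
#'
#' Methods are rows, metrics (or categories) are columns. Failed metric
#' evaluations are serialized as the literal token `NA` so the file is
#' readable from both R and Python.
#'
#' @param table a `score_table`/`rank_table` or any numeric matrix/data frame
#'   with method row names.
#' @param path output path.
#' @param sep field separator; default tab.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path, sep = "\t") {
  if (inherits(table, "score_table")) table <- table$values
  if (inherits(table, "rank_table")) {
    table <- cbind(table$ranks, table$category_scores,
                   overall = table$overall)
  }
  tab <- as.matrix(table)
  if (length(tab) == 0L) stop("table is empty", call. = FALSE)
  df <- data.frame(method = rownames(tab), tab,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_scores()]
#'
#' @param path file written by [write_scores()].
#' @param sep field separator; default tab.
#' @return numeric matrix with method row names; `NA` for failures.
#' @export
read_scores <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, na.strings = "NA")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an expression matrix or embedding to CSV
#'
#' @param X numeric matrix with column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  check_matrix(X, "X")
  utils::write.table(X, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = colnames(X) %||% paste0("V", seq_len(ncol(X))))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
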