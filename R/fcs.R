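# Minimal FCS 3.0/3.1 support: HEADER + TEXT + primary DATA segment only.
# List-mode data, $DATATYPE F (float32) or D (float64), little- or
# big-endian $BYTEORD. Analysis segments, supplemental text, compensation
# and integer data types are out of scope.

#' Read an FCS 3.0/3.1 file
#'
#' Parses the primary data segment of a list-mode FCS file into a
#' cells-by-markers matrix. Marker names are taken from `$PnS` when present,
#' otherwise `$PnN`.
#'
#' @param path path to the FCS file.
#' @return numeric matrix (events x parameters) with marker column names.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version, call. = FALSE)
  off <- function(i) {
    s <- substr(header, 11L + (i - 1L) * 8L, 10L + i * 8L)
    as.numeric(trimws(s))
  }
  txt_beg <- off(1L); txt_end <- off(2L)
  dat_beg <- off(3L); dat_end <- off(4L)

  seek(con, txt_beg)
  txt <- rawToChar(readBin(con, "raw", txt_end - txt_beg + 1L))
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  kw <- stats::setNames(as.list(vals), toupper(trimws(keys)))

  if (dat_beg == 0 && !is.null(kw[["$BEGINDATA"]])) {
    dat_beg <- as.numeric(kw[["$BEGINDATA"]])
    dat_end <- as.numeric(kw[["$ENDDATA"]])
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE ", dtype, " (only F/D)", call. = FALSE)
  if (!is.null(kw[["$MODE"]]) && toupper(kw[["$MODE"]]) != "L")
    stop("only list-mode ($MODE L) FCS is supported", call. = FALSE)
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  size <- if (dtype == "F") 4L else 8L

  seek(con, dat_beg)
  vals <- readBin(con, "double", n = n_par * n_tot, size = size,
                  endian = endian)
  X <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  nm <- vapply(seq_len(n_par), function(i) {
    s <- kw[[paste0("$P", i, "S")]]
    n <- kw[[paste0("$P", i, "N")]]
    if (!is.null(s) && nzchar(s)) s else (n %||% paste0("P", i))
  }, character(1L))
  colnames(X) <- nm
  X
}

#' Write a matrix as a minimal FCS 3.1 file
#'
#' Writes list-mode float32 data with the keywords required for round-trip
#' reading ([read_fcs()]). Intended for interoperability and for generating
#' test inputs; full metadata authoring is not supported.
#'
#' @param X numeric matrix (events x parameters) with column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(X, path) {
  check_matrix(X, "X")
  nm <- colnames(X) %||% paste0("P", seq_len(ncol(X)))
  n_par <- ncol(X); n_tot <- nrow(X)
  d <- "/"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", n_par, "$TOT", n_tot, "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    kv <- c(kv, paste0("$P", i, "N"), nm[i],
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), format(ceiling(max(abs(X[, i]), 1)),
                                         scientific = FALSE))
  }
  txt <- paste0(d, paste(kv, collapse = d), d)
  txt_beg <- 58L
  txt_end <- txt_beg + nchar(txt, type = "bytes") - 1L
  dat_beg <- txt_end + 1L
  dat_end <- dat_beg + 4L * n_par * n_tot - 1L
  pad8 <- function(x) formatC(x, width = 8L)
  header <- paste0("FCS3.1    ", pad8(txt_beg), pad8(txt_end),
                   pad8(dat_beg), pad8(dat_end), pad8(0L), pad8(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(X)), con, size = 4L, endian = "little")
  invisible(path)
}
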