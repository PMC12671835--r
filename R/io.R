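#' Read and write univariate series files
#'
#' `read_series()` parses a one-column (or column-selected) numeric series
#' from a CSV or whitespace-delimited text file. Blank lines and `#`
#' comment lines are skipped, a single header row is auto-detected and
#' skipped, and the decimal separator is always the point regardless of
#' locale. `write_series()` writes a numeric vector one value per line.
#'
#' @param path File path.
#' @param column Column to extract when rows have several fields: a 1-based
#'   index or a header name. Defaults to the first column.
#' @param x Numeric vector to write.
#' @return `read_series()`: a numeric vector. `write_series()`: the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_series(c(1.5, 2.5), f)
#' read_series(f)
#' @export
read_series <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)

  sep <- if (any(grepl(",", lines))) "," else "\\s+"
  split_row <- function(l) {
    f <- strsplit(trimws(l), sep)[[1]]
    f[f != ""]
  }
  rows <- lapply(lines, split_row)

  col_idx <- if (is.null(column)) 1L else column
  header <- suppressWarnings(is.na(as.numeric(rows[[1]][1])))
  if (header) {
    if (is.character(column)) {
      col_idx <- match(column, rows[[1]])
      if (is.na(col_idx))
        stop("column '", column, "' not found in header.", call. = FALSE)
    }
    rows <- rows[-1]
    line_no <- line_no[-1]
  } else if (is.character(column)) {
    stop("column name given but the file has no header row.", call. = FALSE)
  }

  vals <- vapply(seq_along(rows), function(i) {
    f <- rows[[i]]
    if (length(f) < col_idx)
      stop("row ", line_no[i], ": fewer than ", col_idx, " fields.",
           call. = FALSE)
    v <- suppressWarnings(as.numeric(f[col_idx]))
    if (is.na(v))
      stop("row ", line_no[i], ": non-numeric value '", f[col_idx], "'.",
           call. = FALSE)
    v
  }, numeric(1))
  vals
}

#' @rdname read_series
#' @export
write_series <- function(x, path) {
  writeLines(format(x, scientific = FALSE, trim = TRUE, digits = 15), path)
  invisible(path)
}
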