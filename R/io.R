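#' Read a univariate series from a text file
#'
#' Accepts one-value-per-line plain text or a single-column CSV, with or
#' without a header line (a non-numeric first line is treated as a header).
#' Multi-column files are rejected.
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  d <- read.table(path, header = has_header, sep = if (grepl(",", first)) "," else "")
  if (ncol(d) != 1) stop("expected a single-column series file")
  x <- d[[1]]
  if (!is.numeric(x)) stop("series column is not numeric")
  x
}

#' Write a univariate series to a single-column file
#'
#' @param x numeric vector (or a `"sim_series"` object, whose values are
#'   written).
#' @param path output path; a `.csv` extension writes a `value` header,
#'   otherwise bare one-value-per-line text is written.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  if (inherits(x, "sim_series")) x <- x$values
  if (grepl("\\.csv$", path)) {
    write.table(data.frame(value = x), path, sep = ",", row.names = FALSE,
                quote = FALSE)
  } else {
    writeLines(format(x, digits = 17, trim = TRUE, scientific = FALSE), path)
  }
  invisible(path)
}
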