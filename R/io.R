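# Delimited-text I/O for matrices and time series.

#' Read and write numeric matrices as delimited text
#'
#' Reads a numeric matrix (connectivity `A`, noise covariance `Sigma(E)`,
#' a `2N x 2N` joint covariance, or a samples-by-channels time series)
#' from comma-separated text.  A header row is detected automatically: if
#' the first line contains any non-numeric field it is treated as column
#' names.
#'
#' @param path file path.
#' @return `read_matrix_csv()`: a numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.table(path, sep = ",", header = header))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' @rdname read_matrix_csv
#' @param x numeric matrix.
#' @return `write_matrix_csv()`: the path, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.table(
    x, path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
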