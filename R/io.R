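#' CSV serialization of channel matrices
#'
#' Amplitude and stochastic matrices round-trip through CSV with the state
#' order as header row (codons for the 64-state models, bases for the
#' nucleotide models). Complex amplitudes are stored as R complex literals
#' (`"a+bi"`).
#'
#' @param M Matrix with dimnames.
#' @param path CSV file path.
#' @export
write_matrix_csv <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(colnames(M)))
  df <- as.data.frame(format(unclass(M), digits = 17, trim = TRUE,
                             scientific = TRUE))
  utils::write.csv(cbind(state = rownames(M), df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @param complex Parse entries as complex numbers?
#' @return `read_matrix_csv()`: the matrix with dimnames restored.
#' @export
read_matrix_csv <- function(path, complex = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  states <- df$state
  body <- as.matrix(df[, setdiff(names(df), "state"), drop = FALSE])
  M <- if (complex) {
    matrix(as.complex(body), nrow(body), ncol(body))
  } else {
    matrix(as.numeric(body), nrow(body), ncol(body))
  }
  dimnames(M) <- list(states, colnames(body))
  M
}
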