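# Delimited-text readers/writers for the pipeline's on-disk formats.
# TSV by default, CSV by extension; gzip handled transparently by base
# connections. NA tokens: "", "NA", "NaN".

delim_for <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read / write an expression matrix
#'
#' Expression matrices are stored as delimited text with the first column
#' holding sample identifiers and the header row gene identifiers (samples in
#' rows). Use `transpose = TRUE` for files written genes-in-rows.
#'
#' @param path file path (`.tsv`, `.csv`, optionally `.gz`).
#' @param transpose set `TRUE` when the file stores genes in rows.
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
read_expression <- function(path, transpose = FALSE) {
  df <- read.delim(path, sep = delim_for(path), check.names = FALSE,
                   na.strings = c("", "NA", "NaN"), row.names = 1)
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  rownames(m) <- strip_ws(rownames(m))
  colnames(m) <- strip_ws(colnames(m))
  check_expression(m, allow_na = TRUE)
}

#' @rdname read_expression
#' @param expr samples x genes matrix to write.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene universe (one identifier per line)
#' @param path text file path.
#' @return character vector of gene identifiers.
#' @export
read_universe <- function(path) {
  x <- strip_ws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_universe
#' @param universe character vector to write.
#' @export
write_universe <- function(universe, path) {
  writeLines(universe, path)
  invisible(path)
}

#' Read a cohort annotation (sample id, cancer-type label)
#'
#' Two-column delimited file with a header; first column sample id, second
#' the group label.
#' @param path file path.
#' @return named character vector of group labels.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, sep = delim_for(path), na.strings = c("", "NA", "NaN"))
  setNames(strip_ws(df[[2]]), strip_ws(df[[1]]))
}

#' Read a purity-estimate table
#'
#' Delimited file with sample id in the first column, cancer-type label in
#' the second, and one column per genomics purity estimator; blank/NA cells
#' are missing values.
#' @param path file path.
#' @return list with `estimates` (samples x methods matrix, `NA` = missing)
#'   and `groups` (named character vector).
#' @export
read_purity_estimates <- function(path) {
  df <- read.delim(path, sep = delim_for(path), check.names = FALSE,
                   na.strings = c("", "NA", "NaN"))
  ids <- strip_ws(df[[1]])
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  list(estimates = m, groups = setNames(strip_ws(df[[2]]), ids))
}

#' Read / write per-sample purity values (sample id, purity)
#' @param path file path.
#' @return named numeric vector.
#' @export
read_purity <- function(path) {
  df <- read.delim(path, sep = delim_for(path))
  setNames(as.numeric(df[[2]]), strip_ws(df[[1]]))
}

#' @rdname read_purity
#' @param purity named numeric vector in `[0, 1]`.
#' @export
write_purity <- function(purity, path) {
  write.table(data.frame(sample_id = names(purity), purity = unname(purity)),
              path, sep = delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}
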