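# TSV readers and writers. The on-disk dialect is tab-separated, UTF-8,
# '.' decimal separator, header required -- unambiguous across locales.

#' Read a category count table
#'
#' Expects a two-column TSV with header `category<TAB>count`. Malformed
#' rows, negative or non-integer counts and duplicate categories raise
#' parse errors naming the offending line (1-based, including the header).
#'
#' @param path Path to the TSV file.
#' @return A [count_vector()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), c("category", "count"))) {
    stop_invalid("expected header 'category\tcount' in ", path)
  }
  counts <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    stop_invalid("invalid count at line ", bad[1] + 1L, " of ", path,
                 ": '", df$count[bad[1]], "'")
  }
  dup <- which(duplicated(df$category))
  if (length(dup)) {
    stop_invalid("duplicate category at line ", dup[1] + 1L, " of ", path,
                 ": '", df$category[dup[1]], "'")
  }
  count_vector(counts, labels = df$category)
}

#' Write a category count table
#'
#' @param x A [count_vector()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  if (!inherits(x, "count_vector")) x <- count_vector(x)
  utils::write.table(
    data.frame(category = x$labels, count = x$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a subject-by-feature binary matrix
#'
#' First column holds subject identifiers; remaining columns are 0/1
#' features.
#'
#' @param path Path to the TSV file.
#' @return Binary matrix with subject row names.
#' @export
read_binary_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop_invalid("binary matrix needs an ID column plus features")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1))) {
    stop_invalid("feature entries must all be 0 or 1 in ", path)
  }
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a symmetric distance matrix
#'
#' Square TSV with a leading label column and matching column labels.
#' Asymmetries or nonzero diagonal beyond `1e-9` are rejected with the
#' worst offending cell reported; within tolerance the matrix is
#' symmetrized exactly.
#'
#' @param path Path to the TSV file.
#' @return Symmetric numeric distance matrix.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                          row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop_invalid("distance matrix must be square")
  if (!identical(rownames(m), colnames(m))) {
    stop_invalid("row and column labels differ in ", path)
  }
  validate_distance_matrix(m)
}

#' Write a distance matrix
#'
#' @param d Symmetric distance matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  d <- validate_distance_matrix(d)
  labs <- rownames(d) %||% as.character(seq_len(nrow(d)))
  out <- data.frame(label = labs, d, check.names = FALSE)
  names(out) <- c("label", labs)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a univariate numeric series
#'
#' Accepts a one-column TSV/CSV (with or without header) of numeric values.
#'
#' @param path Path to the file.
#' @return Numeric vector.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  vals <- raw[[1]]
  first <- suppressWarnings(as.numeric(vals[1]))
  if (is.na(first)) vals <- vals[-1] # header line
  x <- suppressWarnings(as.numeric(vals))
  if (anyNA(x)) {
    stop_invalid("non-numeric value in series at entry ", which(is.na(x))[1])
  }
  x
}
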