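#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: argument checking, pair keys,
## fast row-wise Pearson correlation, and the TSV dialect used throughout
## (single header row, identifiers in column 1, tab-separated, no quoting).

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .stopf("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    .stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    .stopf("'%s' must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

## Canonical key for an unordered gene pair.
.pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}

## Row-wise Pearson correlation between two matrices of equal shape
## (one observation vector per row). Returns NA for constant rows.
.row_cor <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  den <- sqrt(rowSums(Xc * Xc) * rowSums(Yc * Yc))
  r <- rowSums(Xc * Yc) / den
  r[den == 0] <- NA_real_
  r
}

## Pearson r between two plain vectors with an explicit constant-vector error.
.cor_strict <- function(x, y, what = "vector") {
  if (length(x) != length(y)) .stopf("paired vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .stopf("undefined correlation: constant %s", what)
  }
  stats::cor(x, y)
}

## ---- TSV dialect ----------------------------------------------------------

#' Read a numeric matrix in the pipeline's TSV dialect
#'
#' Column 1 holds row identifiers (genes or probes), the header row holds
#' sample identifiers. Duplicated identifiers and non-numeric cells are
#' errors that name the offending file.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    .stopf("duplicate row identifier '%s' in %s", ids[duplicated(ids)][1L], path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) .stopf("non-numeric matrix cell in %s", path)
  rownames(m) <- ids
  m
}

#' Write a numeric matrix in the pipeline's TSV dialect
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_name Header label for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV table with a header row
#' @param path Path to a tab-separated file.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a plain TSV table with a header row
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
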