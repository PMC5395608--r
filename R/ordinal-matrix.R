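#' Ordinal response matrices
#'
#' An `ordinal_matrix` is an n x m integer matrix of questionnaire responses
#' on the ordered category set \{1, ..., q\}: one row per respondent, one
#' column per item. It is the common container for both the observed
#' (suspected-fake) matrix F and the true/reconstructed matrix D. Missing
#' entries are rejected: incomplete respondents must be removed before
#' ingest, they are never imputed.
#'
#' @param values an integer matrix (or something coercible to one) with all
#'   entries in \{1, ..., q\} and no missing values.
#' @param q number of ordinal categories (integer >= 2).
#' @return an object of class `ordinal_matrix`: the integer matrix with
#'   attribute `q`.
#' @examples
#' x <- ordinal_matrix(matrix(c(1L, 3L, 5L, 2L), 2, 2), q = 5)
#' n_categories(x)
#' @export
ordinal_matrix <- function(values, q) {
  if (!is.matrix(values)) values <- as.matrix(values)
  q <- as.integer(q)
  if (length(q) != 1L || is.na(q) || q < 2L)
    stop("`q` must be a single integer >= 2", call. = FALSE)
  if (length(values) == 0L)
    stop("response matrix is empty", call. = FALSE)
  if (anyNA(values))
    stop("response matrix contains missing entries; remove incomplete respondents before ingest",
         call. = FALSE)
  if (!is.numeric(values))
    stop("response matrix must be numeric", call. = FALSE)
  iv <- as.integer(round(values))
  if (max(abs(values - iv)) > 1e-8)
    stop("response matrix contains non-integer values", call. = FALSE)
  values <- matrix(iv, nrow(values), ncol(values), dimnames = dimnames(values))
  bad <- which(values < 1L | values > q, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("value %d at row %d, column %d outside {1..%d}",
                 values[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], q),
         call. = FALSE)
  structure(values, q = q, class = c("ordinal_matrix", "matrix", "array"))
}

#' @rdname ordinal_matrix
#' @param x an `ordinal_matrix`.
#' @export
n_categories <- function(x) {
  stopifnot(inherits(x, "ordinal_matrix"))
  attr(x, "q")
}

#' @export
print.ordinal_matrix <- function(x, ...) {
  cat(sprintf("ordinal_matrix: %d respondents x %d items, categories 1..%d\n",
              nrow(x), ncol(x), attr(x, "q")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("... (%d more rows)\n", nrow(x) - 6L))
  invisible(x)
}

as_plain_matrix <- function(x) {
  attr(x, "q") <- NULL
  class(x) <- NULL
  matrix(as.integer(x), nrow(x), ncol(x))
}
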