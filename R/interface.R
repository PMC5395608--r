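#' Read a response matrix from CSV
#'
#' One row per respondent, one integer column per item; an optional header
#' row is auto-detected (non-numeric first line). Non-integer, out-of-range
#' or missing cells abort with an error naming the offending row and
#' column — incomplete respondents must be removed upstream, never imputed.
#'
#' @param path CSV file path.
#' @param q number of ordinal categories the values are validated against.
#' @return an [ordinal_matrix()].
#' @export
read_response_matrix <- function(path, q) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop(sprintf("empty response file: %s", path), call. = FALSE)
  has_header <- anyNA(suppressWarnings(as.numeric(strsplit(first, ",")[[1]])))
  df <- utils::read.csv(path, header = has_header, colClasses = "numeric",
                        check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)
  mat <- as.matrix(df)
  na <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(na) > 0L)
    stop(sprintf("missing or non-numeric cell at row %d, column %d of %s",
                 na[1, 1], na[1, 2], path), call. = FALSE)
  x <- tryCatch(ordinal_matrix(mat, q), error = function(e)
    stop(sprintf("%s (file %s)", conditionMessage(e), path), call. = FALSE))
  x
}

#' Write a response matrix to CSV
#'
#' Plain integer CSV with a header row (`item1..itemM`); the round trip
#' through [read_response_matrix()] is the identity.
#'
#' @param x an [ordinal_matrix()].
#' @param path output CSV path.
#' @export
write_response_matrix <- function(x, path) {
  stopifnot(inherits(x, "ordinal_matrix"))
  m <- as_plain_matrix(x)
  colnames(m) <- paste0("item", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build synthetic honest/fake fixtures
#'
#' Composes the generator and the forward (corruption) perturbation to
#' emulate an honest matrix D, a fake-good matrix F, or the matched pair
#' (D, F) with F a forward perturbation of D (so F >= D entrywise).
#'
#' @param kind `"true_data"`, `"fake_data"` or `"paired"`.
#' @param gen a [generative_params()] object.
#' @param corruption a [replacement_params()] with direction `"forward"`;
#'   required unless `kind = "true_data"`.
#' @param seed integer seed for the whole fixture.
#' @return an [ordinal_matrix()], or for `"paired"` a list with elements
#'   `D` and `F`.
#' @export
make_fixture <- function(kind = c("paired", "true_data", "fake_data"),
                         gen, corruption = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(gen, "generative_params"))
  seed <- as.integer(seed)
  d <- generate_true_data(gen, seed = seed)
  if (kind == "true_data") return(d)
  if (is.null(corruption) || corruption$direction != "forward")
    stop("`corruption` must be forward-direction replacement_params", call. = FALSE)
  f <- perturb_matrix(d, corruption, seed = seed + 1L)
  switch(kind, fake_data = f, paired = list(D = d, F = f))
}

#' Read/write run configuration
#'
#' JSON round trip for a run configuration: grid parameters (scenarios,
#' pi_grid, B, q, seed), optional generative parameters, and paths. Every
#' pipeline run echoes its effective configuration into the output
#' directory so the run can be reproduced bit-for-bit.
#'
#' @param path JSON file path.
#' @param config named list to serialize.
#' @return `read_run_config` returns the named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
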