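#' Discrete generalized beta probability mass function
#'
#' Two-shape-parameter mass family on the bounded integer support
#' \{a, ..., b\}: the mass at h is proportional to
#' (h - a + 1)^(gamma - 1) * (b - h + 1)^(delta - 1), normalized to sum to
#' one. With gamma = delta = 1 it reduces to the discrete uniform; gamma >
#' delta piles mass near the upper bound, gamma < delta near the lower bound.
#' It controls where a replaced response value lands.
#'
#' @param a integer lower bound of the support.
#' @param b integer upper bound, b >= a.
#' @param gamma,delta strictly positive shape parameters.
#' @return numeric probability vector over a:b, summing to one.
#' @examples
#' dg_pmf(1, 4, 1, 1)      # uniform
#' dg_pmf(1, 4, 4, 1.5)    # mass concentrated near the upper bound
#' @export
dg_pmf <- function(a, b, gamma, delta) {
  if (b < a) stop("empty support: b < a", call. = FALSE)
  if (gamma <= 0 || delta <= 0)
    stop("shape parameters gamma and delta must be > 0", call. = FALSE)
  h <- a:b
  # log scale guards against overflow for large shapes/supports
  lw <- (gamma - 1) * log(h - a + 1) + (delta - 1) * log(b - h + 1)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Replacement model parameters
#'
#' Bundles the shape pair (gamma, delta), the overall per-entry replacement
#' probability pi, and the direction of the perturbation. Direction
#' `"reverse"` reconstructs hypothetical honest data from fake-good
#' responses (values can only be lowered); `"forward"` corrupts honest data
#' into fake-good responses (values can only be raised).
#'
#' @param gamma,delta strictly positive shape parameters of the discrete
#'   generalized beta replacement distribution.
#' @param pi per-entry replacement probability in [0, 1].
#' @param direction `"reverse"` or `"forward"`.
#' @return a `replacement_params` object.
#' @seealso [scenario_params()] for the three canonical scenarios.
#' @export
replacement_params <- function(gamma, delta, pi, direction = c("reverse", "forward")) {
  direction <- match.arg(direction)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 ||
      !is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("gamma and delta must be single positive numbers", call. = FALSE)
  if (!is.numeric(pi) || length(pi) != 1L || pi < 0 || pi > 1)
    stop("pi must be a single probability in [0, 1]", call. = FALSE)
  structure(list(gamma = gamma, delta = delta, pi = pi, direction = direction),
            class = "replacement_params")
}

# canonical (gamma, delta) pairs, reverse-direction parameterization
.scenario_shapes <- list(
  uninformative = c(gamma = 1,   delta = 1),
  slight        = c(gamma = 4,   delta = 1.5),
  extreme       = c(gamma = 1.5, delta = 4)
)

#' Canonical faking-scenario parameters
#'
#' The three graded faking scenarios: `"uninformative"` (gamma = delta = 1,
#' uniform replacement), `"slight"` (gamma = 4, delta = 1.5; replaced values
#' land mostly adjacent to the original, small shifts), and `"extreme"`
#' (gamma = 1.5, delta = 4; replaced values land mostly far from the
#' original, large shifts). In the forward direction the shape pair is
#' swapped so that a scenario name keeps its meaning (slight = small shifts)
#' in both directions.
#'
#' @param name one of `"uninformative"`, `"slight"`, `"extreme"`.
#' @param pi per-entry replacement probability in [0, 1].
#' @param direction `"reverse"` or `"forward"`.
#' @return a [replacement_params()] object.
#' @examples
#' scenario_params("slight", pi = 0.25)
#' @export
scenario_params <- function(name, pi, direction = c("reverse", "forward")) {
  direction <- match.arg(direction)
  if (length(name) != 1L || !name %in% names(.scenario_shapes))
    stop(sprintf("unknown scenario '%s'; use one of: %s",
                 paste(name, collapse = ","),
                 paste(names(.scenario_shapes), collapse = ", ")),
         call. = FALSE)
  sh <- .scenario_shapes[[name]]
  if (direction == "forward") sh <- c(gamma = unname(sh["delta"]), delta = unname(sh["gamma"]))
  p <- replacement_params(sh[["gamma"]], sh[["delta"]], pi, direction)
  p$scenario <- name
  p
}

#' @export
print.replacement_params <- function(x, ...) {
  cat(sprintf("replacement_params: gamma=%g delta=%g pi=%g direction=%s%s\n",
              x$gamma, x$delta, x$pi, x$direction,
              if (!is.null(x$scenario)) paste0(" (", x$scenario, ")") else ""))
  invisible(x)
}

#' Conditional replacement distribution of a single response value
#'
#' Probability vector over \{1, ..., q\} for the value that replaces an
#' observed response k. In the reverse direction (reconstruction of honest
#' data from fake-good data): k = 1 is absorbing; for k > 1 the original
#' value is kept with probability 1 - pi and otherwise replaced by a draw
#' from the discrete generalized beta over \{1, ..., k - 1\}; values above k
#' get zero mass. The forward direction is the mirror image on
#' \{k + 1, ..., q\} with the shape parameters swapped.
#'
#' @param k observed value in \{1, ..., q\}.
#' @param params a [replacement_params()] object.
#' @param q number of ordinal categories.
#' @return numeric probability vector of length q, summing to one.
#' @examples
#' replacement_pmf(5, scenario_params("uninformative", 0.6), q = 5)
#' @export
replacement_pmf <- function(k, params, q) {
  stopifnot(inherits(params, "replacement_params"))
  q <- as.integer(q)
  if (length(k) != 1L || k < 1 || k > q || k != round(k))
    stop(sprintf("k must be an integer in {1..%d}", q), call. = FALSE)
  k <- as.integer(k)
  p <- numeric(q)
  if (params$direction == "reverse") {
    if (k == 1L) { p[1L] <- 1; return(p) }
    p[k] <- 1 - params$pi
    p[1:(k - 1L)] <- params$pi * dg_pmf(1L, k - 1L, params$gamma, params$delta)
  } else {
    if (k == q) { p[q] <- 1; return(p) }
    p[k] <- 1 - params$pi
    p[(k + 1L):q] <- params$pi * dg_pmf(k + 1L, q, params$gamma, params$delta)
  }
  p
}

#' Entrywise stochastic perturbation of an ordinal matrix
#'
#' Replaces every entry of `data` by an independent draw from its
#' conditional replacement distribution ([replacement_pmf()]). Reverse
#' direction never increases an entry; forward never decreases one. A single
#' uniform stream is consumed in row-major order, so the result is a
#' deterministic function of (`data`, `params`, `seed`).
#'
#' @param data an [ordinal_matrix()].
#' @param params a [replacement_params()] object.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an [ordinal_matrix()] of the same dimension.
#' @examples
#' f <- ordinal_matrix(matrix(5L, 4, 3), q = 5)
#' perturb_matrix(f, scenario_params("slight", 0.5), seed = 1)
#' @export
perturb_matrix <- function(data, params, seed = NULL) {
  stopifnot(inherits(data, "ordinal_matrix"), inherits(params, "replacement_params"))
  q <- n_categories(data)
  n <- nrow(data); m <- ncol(data)
  if (!is.null(seed)) set.seed(as.integer(seed))
  # one uniform per entry, consumed row-major; inverse-CDF draw per entry
  u <- t(matrix(stats::runif(n * m), nrow = m))
  v <- as_plain_matrix(data)
  out <- v
  for (k in seq_len(q)) {
    idx <- which(v == k)
    if (length(idx) == 0L) next
    cdf <- cumsum(replacement_pmf(k, params, q))
    cdf[q] <- 1  # close roundoff at the top
    out[idx] <- findInterval(u[idx], cdf, left.open = TRUE) + 1L
  }
  ordinal_matrix(out, q)
}
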