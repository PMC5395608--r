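#' One-factor confirmatory factor analysis by maximum likelihood
#'
#' Fits the model Sigma(theta) = lambda lambda' + diag(psi) to the sample
#' covariance of integer item scores by minimizing the ML discrepancy
#' F = log|Sigma| - log|S| + tr(S Sigma^-1) - m, with chi-square
#' (n - 1) * F at the optimum. Uniquenesses are left unconstrained so
#' Heywood cases (negative error variances) can occur and be flagged as
#' improper rather than silenced; see [flag_improper()]. Loading signs are
#' resolved by forcing a nonnegative mean loading.
#'
#' This is a deliberately simple Pearson-covariance ML estimator for
#' comparative Monte-Carlo use on ordinal scores; it is not a
#' polychoric/weighted least squares estimator.
#'
#' @param data an [ordinal_matrix()], or a sample covariance matrix (then
#'   `n` must be given).
#' @param n sample size when `data` is a covariance matrix.
#' @param max_iter optimizer iteration cap (default 500).
#' @return a `cfa_result` list: `loadings`, `uniquenesses`, `chi2_model`,
#'   `df_model`, `chi2_baseline`, `df_baseline`, `nfi`, `cfi`, `nnfi`,
#'   `rmsea`, `converged`, `proper`, `improper_reasons`.
#' @examples
#' s <- matrix(0.25, 12, 12); diag(s) <- 1
#' fit <- fit_one_factor(s, n = 200)
#' fit$loadings[1]  # 0.5 = sqrt(0.25)
#' @export
fit_one_factor <- function(data, n = NULL, max_iter = 500L) {
  if (inherits(data, "ordinal_matrix")) {
    n <- nrow(data)
    s <- stats::cov(as_plain_matrix(data))
  } else {
    s <- as.matrix(data)
    if (is.null(n)) stop("`n` is required when passing a covariance matrix", call. = FALSE)
  }
  m <- ncol(s)
  if (m < 3L) stop("one-factor model needs at least 3 items for identification", call. = FALSE)
  if (any(diag(s) <= 0)) stop("sample covariance has non-positive diagonal", call. = FALSE)
  ldS <- determinant(s, logarithm = TRUE)
  if (ldS$sign <= 0 || !is.finite(ldS$modulus))
    stop("singular sample covariance", call. = FALSE)
  ldS <- as.numeric(ldS$modulus)

  discrepancy <- function(theta) {
    lam <- theta[1:m]; psi <- theta[(m + 1):(2 * m)]
    sigma <- tcrossprod(lam) + diag(psi, m)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldSig <- 2 * sum(log(diag(ch)))
    ldSig - ldS + sum(diag(chol2inv(ch) %*% s)) - m
  }
  gradient <- function(theta) {
    lam <- theta[1:m]; psi <- theta[(m + 1):(2 * m)]
    sigma <- tcrossprod(lam) + diag(psi, m)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, 2 * m))
    inv <- chol2inv(ch)
    a <- inv - inv %*% s %*% inv  # dF/dSigma (up to symmetry weights)
    c(2 * as.vector(a %*% lam), diag(a))
  }

  # start: first principal component pattern
  ev <- eigen(s, symmetric = TRUE)
  lam0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 1e-8))
  if (mean(lam0) < 0) lam0 <- -lam0
  psi0 <- pmax(diag(s) - lam0^2, 0.05 * diag(s))
  opt <- stats::optim(c(lam0, psi0), discrepancy, gradient, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  lam <- opt$par[1:m]; psi <- opt$par[(m + 1):(2 * m)]
  if (mean(lam) < 0) lam <- -lam
  gnorm <- sqrt(sum(gradient(opt$par)^2))
  converged <- (opt$convergence == 0L || gnorm < 1e-6) && opt$value < 1e9

  chi2_m <- max((n - 1) * opt$value, 0)
  df_m <- m * (m + 1) / 2 - 2 * m
  bl <- baseline_chi_square(s, n)
  idx <- compute_fit_indices(chi2_m, df_m, bl$chi2_baseline, bl$df_baseline, n)
  if (idx$undefined) converged <- FALSE  # zero-baseline degenerate replicate

  res <- list(loadings = lam, uniquenesses = psi,
              chi2_model = chi2_m, df_model = as.integer(df_m),
              chi2_baseline = bl$chi2_baseline, df_baseline = bl$df_baseline,
              nfi = idx$nfi, cfi = idx$cfi, nnfi = idx$nnfi, rmsea = idx$rmsea,
              converged = converged, n = n)
  fl <- flag_improper(res)
  res$proper <- fl$proper
  res$improper_reasons <- fl$reasons
  class(res) <- "cfa_result"
  res
}

#' @export
print.cfa_result <- function(x, ...) {
  cat(sprintf("one-factor CFA (n = %d, m = %d)\n", x$n, length(x$loadings)))
  cat("loadings:     ", paste(sprintf("%.3f", x$loadings), collapse = " "), "\n")
  cat("uniquenesses: ", paste(sprintf("%.3f", x$uniquenesses), collapse = " "), "\n")
  cat(sprintf("chi2 = %.4f (df %d), baseline chi2 = %.4f (df %d)\n",
              x$chi2_model, x$df_model, x$chi2_baseline, x$df_baseline))
  cat(sprintf("NFI %.3f  CFI %.3f  NNFI %.3f  RMSEA %.3f\n",
              x$nfi, x$cfi, x$nnfi, x$rmsea))
  cat(sprintf("converged: %s  proper: %s%s\n", x$converged, x$proper,
              if (!x$proper) paste0(" (", paste(x$improper_reasons, collapse = "; "), ")") else ""))
  invisible(x)
}

#' Independence-baseline chi-square
#'
#' ML discrepancy of the independence model Sigma_b = diag(S), which
#' reduces to -(n - 1) * log|R| with R the sample correlation matrix;
#' degrees of freedom m(m - 1)/2. Needed by the incremental fit indices.
#'
#' @param s sample covariance matrix. @param n sample size.
#' @return list with `chi2_baseline` and `df_baseline`.
#' @export
baseline_chi_square <- function(s, n) {
  s <- as.matrix(s)
  m <- ncol(s)
  r <- stats::cov2cor(s)
  ld <- determinant(r, logarithm = TRUE)
  if (ld$sign <= 0) stop("singular sample covariance", call. = FALSE)
  list(chi2_baseline = max(-(n - 1) * as.numeric(ld$modulus), 0),
       df_baseline = as.integer(m * (m - 1) / 2))
}

#' Fit indices from model and baseline chi-squares
#'
#' Standard definitions: NFI = (chi2_b - chi2_m)/chi2_b;
#' NNFI (TLI) = (chi2_b/df_b - chi2_m/df_m)/(chi2_b/df_b - 1);
#' CFI = 1 - max(chi2_m - df_m, 0)/max(chi2_b - df_b, chi2_m - df_m, 0);
#' RMSEA = sqrt(max(chi2_m - df_m, 0)/(df_m (n - 1))). NNFI may exceed 1.
#' A zero baseline chi-square leaves the indices undefined and is flagged.
#'
#' @param chi2_m,df_m model chi-square and degrees of freedom.
#' @param chi2_b,df_b baseline chi-square and degrees of freedom.
#' @param n sample size.
#' @return list `nfi`, `cfi`, `nnfi`, `rmsea`, `undefined`.
#' @export
compute_fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n) {
  if (chi2_b <= 0 || df_m <= 0)
    return(list(nfi = NA_real_, cfi = NA_real_, nnfi = NA_real_,
                rmsea = NA_real_, undefined = TRUE))
  nfi <- (chi2_b - chi2_m) / chi2_b
  nnfi <- (chi2_b / df_b - chi2_m / df_m) / (chi2_b / df_b - 1)
  denom <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2_m - df_m, 0) / denom
  rmsea <- sqrt(max(chi2_m - df_m, 0) / (df_m * (n - 1)))
  list(nfi = nfi, cfi = cfi, nnfi = nnfi, rmsea = rmsea, undefined = FALSE)
}

#' Flag improper factor solutions
#'
#' A solution is improper when any uniqueness (error variance) is negative
#' — a Heywood case — or any loading exceeds 10 in absolute value. Improper
#' replicates are excluded from Monte-Carlo summaries.
#'
#' @param result a `cfa_result` or any list with `loadings` and
#'   `uniquenesses`.
#' @return list with `proper` flag and character vector `reasons`.
#' @export
flag_improper <- function(result) {
  reasons <- character()
  neg <- which(result$uniquenesses < 0)
  if (length(neg))
    reasons <- c(reasons, sprintf("negative variance (item %s)",
                                  paste(neg, collapse = ",")))
  big <- which(abs(result$loadings) > 10)
  if (length(big))
    reasons <- c(reasons, sprintf("loading > 10 in absolute value (item %s)",
                                  paste(big, collapse = ",")))
  list(proper = length(reasons) == 0L, reasons = reasons)
}
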