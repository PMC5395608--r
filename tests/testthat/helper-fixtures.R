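# shared fixture builders; everything is generated in code, no stored data

random_ordinal <- function(n, m, q, seed) {
  set.seed(seed)
  ordinal_matrix(matrix(sample.int(q, n * m, replace = TRUE), n, m), q)
}

# population covariance of an exact one-factor model
one_factor_cov <- function(lambda, psi) {
  tcrossprod(lambda) + diag(psi, length(lambda))
}

all_scenarios <- c("uninformative", "slight", "extreme")
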