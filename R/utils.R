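# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp; safe for log-likelihood differences up to +-700.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Derive a reproducible 31-bit sub-seed from a master seed and an offset.
# Keeps every derived seed strictly below 2^31 so it is a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 1000003) %%
               2147483587)
}

# Draw n rows from N(0, sigma) via the Cholesky factor.
rmvnorm_chol <- function(n, sigma) {
  d <- ncol(sigma)
  matrix(stats::rnorm(n * d), n, d) %*% chol(sigma)
}

# Symmetrize and, where needed, project a covariance to the nearest positive
# definite matrix by flooring its eigenvalues.
make_positive_definite <- function(sigma, floor = 1e-8) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) > floor) return(sigma)
  vals <- pmax(ev$values, floor)
  ev$vectors %*% (vals * t(ev$vectors))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
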