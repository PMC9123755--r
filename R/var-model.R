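#' Construct a single-class VAR model
#'
#' Bundles the parameters of one latent class: the lagged coefficient
#' matrices, the covariate/intercept coefficients, the innovation covariance
#' and the mixing proportion. Convention: `A[[l]][i, j]` is the effect of
#' variable `j` at lag `l` on variable `i`; `B[i, q]` is the effect of
#' covariate column `q` (column 1 = intercept) on variable `i`.
#'
#' @param lag Lag order `p` (a positive integer).
#' @param A List of `p` square coefficient matrices (`n_vars` x `n_vars`).
#' @param B Covariate coefficient matrix, `n_vars` x (1 + n_covariates);
#'   the first column is the intercept.
#' @param Sigma Innovation covariance matrix; must be symmetric positive
#'   definite.
#' @param pi Mixing proportion in (0, 1].
#'
#' @return An object of class `var_cluster_model`.
#' @export
var_cluster_model <- function(lag, A, B, Sigma, pi = 1) {
  stopifnot(is_count(lag), lag >= 1, is.list(A), length(A) == lag)
  Sigma <- as.matrix(Sigma)
  d <- nrow(Sigma)
  if (ncol(Sigma) != d) stop("Sigma must be square")
  for (l in seq_len(lag)) {
    A[[l]] <- as.matrix(A[[l]])
    if (!all(dim(A[[l]]) == c(d, d)))
      stop(sprintf("A[[%d]] must be %d x %d", l, d, d))
  }
  B <- as.matrix(B)
  if (nrow(B) != d) stop("B must have n_vars rows")
  if (max(abs(Sigma - t(Sigma))) > 1e-8) stop("Sigma must be symmetric")
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi > 1)
    stop("pi must lie in (0, 1]")
  structure(list(lag = as.integer(lag), A = A, B = B,
                 Sigma = (Sigma + t(Sigma)) / 2, pi = pi),
            class = "var_cluster_model")
}

#' Companion matrix of a VAR(p) coefficient set
#'
#' Stacks the lag matrices into the `(d*p) x (d*p)` companion form whose
#' eigenvalues determine stability of the process.
#'
#' @param A List of `p` coefficient matrices, or a `var_cluster_model`.
#' @return The companion matrix.
#' @export
companion_matrix <- function(A) {
  if (inherits(A, "var_cluster_model")) A <- A$A
  p <- length(A)
  d <- nrow(A[[1L]])
  top <- do.call(cbind, A)
  if (p == 1L) return(top)
  rbind(top, cbind(diag(d * (p - 1L)), matrix(0, d * (p - 1L), d)))
}

#' Spectral radius of a VAR coefficient set
#'
#' The process is (covariance) stationary iff this is strictly below 1.
#'
#' @inheritParams companion_matrix
#' @return Largest eigenvalue modulus of the companion matrix.
#' @export
spectral_radius <- function(A) {
  cm <- companion_matrix(A)
  max(Mod(eigen(cm, only.values = TRUE)$values))
}

#' @export
print.var_cluster_model <- function(x, ...) {
  d <- nrow(x$Sigma)
  cat(sprintf("VAR cluster model: %d variables, lag %d, pi = %.3f\n",
              d, x$lag, x$pi))
  cat(sprintf("  spectral radius %.3f; %d covariate column(s)\n",
              spectral_radius(x), ncol(x$B)))
  invisible(x)
}
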