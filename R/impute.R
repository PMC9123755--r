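#' Chained-equations single imputation
#'
#' Fills item-level missing values by iterated conditional regressions
#' ("chained equations"): missing cells are initialised with variable means,
#' then each variable with missing data is regressed on all other variables
#' (pooled across all occasions of all participants) and its missing cells
#' are redrawn from the Bayesian predictive distribution — coefficient and
#' residual-variance draws followed by a noise draw (`method = "norm"`), or
#' predictive-mean matching against the five nearest observed donors
#' (`method = "pmm"`). The chain runs for a fixed number of sweeps
#' (default 500) and is deterministic under `seed`. Observed cells are never
#' altered; imputed values are clamped to [0, 100] when `clamp` is on.
#'
#' Pooling occasions across participants means the imputation model has no
#' participant-level random effects; see the methods vignette for the
#' implications.
#'
#' @param panel An [ema_panel()].
#' @param n_iterations Number of chained-equation sweeps (default 500).
#' @param seed Integer seed.
#' @param clamp Clamp imputed values to the 0-100 slider scale? Default on;
#'   turned off automatically for standardized panels.
#' @param method `"norm"` (Bayesian-draw linear regression, default) or
#'   `"pmm"` (predictive-mean matching).
#' @return The panel with no missing values; attribute `"imputed_cells"`
#'   records how many cells were filled.
#' @export
impute_chained <- function(panel, n_iterations = 500, seed = 1,
                           clamp = !panel$standardized,
                           method = c("norm", "pmm")) {
  method <- match.arg(method)
  stopifnot(is_count(n_iterations), n_iterations >= 1)
  M <- panel_values(panel)
  mis <- is.na(M)
  if (!any(mis)) return(panel)
  all_missing <- which(colSums(!mis) == 0L)
  if (length(all_missing))
    stop("variable missing at every occasion: ",
         panel$variable_names[all_missing[1L]])
  frac <- mean(mis)
  if (!any(colSums(mis) == 0L) && frac >= 0.5)
    stop(sprintf(
      "overall missingness %.0f%% with no fully observed variable; refusing to impute",
      100 * frac))

  set.seed(as.integer(seed))
  # Mean initialisation.
  mu <- colMeans(M, na.rm = TRUE)
  for (j in seq_len(ncol(M))) M[mis[, j], j] <- mu[j]

  need <- which(colSums(mis) > 0L)
  for (it in seq_len(n_iterations)) {
    for (j in need) {
      obs <- !mis[, j]
      X <- cbind(1, M[, -j, drop = FALSE])
      y <- M[, j]
      q <- ncol(X)
      XtX <- crossprod(X[obs, , drop = FALSE])
      diag(XtX) <- diag(XtX) + 1e-8
      R <- chol(XtX)
      beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X[obs, , drop = FALSE],
                                                            y[obs])))
      res <- y[obs] - X[obs, , drop = FALSE] %*% beta_hat
      df <- max(1L, sum(obs) - q)
      sigma2 <- sum(res ^ 2) / stats::rchisq(1L, df)
      beta <- beta_hat + backsolve(R, stats::rnorm(q)) * sqrt(sigma2)
      pred_mis <- as.numeric(X[!obs, , drop = FALSE] %*% beta)
      if (method == "norm") {
        imp <- pred_mis + stats::rnorm(length(pred_mis)) * sqrt(sigma2)
      } else {
        pred_obs <- as.numeric(X[obs, , drop = FALSE] %*% beta)
        y_obs <- y[obs]
        imp <- vapply(pred_mis, function(p) {
          donors <- order(abs(pred_obs - p))[seq_len(min(5L, length(y_obs)))]
          y_obs[donors[sample.int(length(donors), 1L)]]
        }, numeric(1))
      }
      if (clamp) imp <- pmin(pmax(imp, 0), 100)
      M[!obs, j] <- imp
    }
  }
  out <- panel_set_values(panel, M)
  attr(out, "imputed_cells") <- sum(mis)
  out
}
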