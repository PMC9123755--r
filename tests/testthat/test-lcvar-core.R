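test_that("conditional log-likelihood matches direct density evaluation", {
  # Univariate AR(1) with coefficient 0.5, unit variance, series (0, 1, 0.5):
  # residuals are 1 and 0, so logL = 2 dnorm terms = -2.337877.
  panel <- series_panel(c(0, 1, 0.5), beeps_per_day = 3)
  dp <- build_design(panel, 1, covariates = "none")
  m <- var_cluster_model(1, list(matrix(0.5)), matrix(0), matrix(1))
  expect_equal(conditional_loglik(dp, m), -2.337877, tolerance = 1e-6)
  expect_equal(conditional_loglik(dp, m),
               sum(dnorm(c(1, 0.5), mean = 0.5 * c(0, 1), log = TRUE)),
               tolerance = 1e-12)

  # Zero residuals, unit variance: logL = -m*d/2 * ln(2*pi).
  dz <- manual_design(matrix(0, 7, 2, dimnames = list(NULL, c("a", "b"))),
                      cbind(1, matrix(0, 7, 2)), rep("A", 7), 1, 1)
  mz <- var_cluster_model(1, list(matrix(0, 2, 2)), matrix(0, 2, 1), diag(2))
  expect_equal(conditional_loglik(dz, mz), -7 * 2 / 2 * log(2 * pi))

  # Doubling Sigma's diagonal strictly lowers logL at zero residuals.
  m2 <- var_cluster_model(1, list(matrix(0, 2, 2)), matrix(0, 2, 1),
                          diag(2, 2))
  expect_lt(conditional_loglik(dz, m2), conditional_loglik(dz, mz))
})

test_that("the E-step normalises responsibilities correctly", {
  sp <- recovery_sim(1, n = 6)
  dp <- build_design(sp$panel, 1)
  m <- recovery_models(1)[[1]]
  m$B <- matrix(0, 4, 6); m$B[, 1] <- 50 * (diag(4) - m$A[[1]]) %*% rep(1, 4)
  # K identical models: every responsibility is exactly 1/K.
  r2 <- e_step(dp, list(m, m), c(0.5, 0.5))
  expect_lt(max(abs(r2 - 0.5)), 1e-12)
  r1 <- e_step(dp, list(m), 1)
  expect_true(all(r1 == 1))

  # Well-separated univariate intercept models vs a brute-force oracle.
  set.seed(101)
  panel <- series_panel(round(rnorm(20, 5, 1) + 45, 2), beeps_per_day = 5)
  dpu <- build_design(panel, 1, covariates = "none")
  mu_hi <- var_cluster_model(1, list(matrix(0)), matrix(50), matrix(1))
  mu_lo <- var_cluster_model(1, list(matrix(0)), matrix(40), matrix(1))
  r <- e_step(dpu, list(mu_hi, mu_lo), c(0.5, 0.5))
  y <- dpu$outcomes[, 1]
  l_hi <- sum(dnorm(y, 50, 1, log = TRUE))
  l_lo <- sum(dnorm(y, 40, 1, log = TRUE))
  oracle <- exp(l_hi) / (exp(l_hi) + exp(l_lo))
  expect_equal(unname(r[1, 1]), oracle, tolerance = 1e-6)
  expect_gt(r[1, 1], 1 - 1e-6)
})

test_that("the M-step solves the weighted least-squares problem", {
  set.seed(33)
  n_rows <- 120
  X <- cbind(1, matrix(runif(n_rows * 4, -1, 1), n_rows))
  C_true <- cbind(c(0.5, -0.2), matrix(c(0.3, 0.1, -0.1, 0.25,
                                         0.05, -0.3, 0.2, 0.15), 2))
  Y <- X %*% t(C_true) + matrix(rnorm(n_rows * 2, sd = 0.3), n_rows)
  colnames(Y) <- c("a", "b")
  dp <- manual_design(Y, X, rep(sprintf("P%02d", 1:12), each = 10), 1, 2)
  resp <- matrix(1, 12, 1)
  ms <- m_step(dp, resp, lags = 2, min_members = 1)
  # OLS oracle by direct normal equations.
  C_ols <- t(solve(crossprod(X), crossprod(X, Y)))
  expect_equal(model_coefmat_for_test(ms$clusters[[1]]), unname(C_ols),
               tolerance = 1e-8)

  # Exact interpolation with zero noise.
  Y0 <- X %*% t(C_true); colnames(Y0) <- c("a", "b")
  dp0 <- manual_design(Y0, X, dp$row_participant, 1, 2)
  ms0 <- m_step(dp0, resp, lags = 2, min_members = 1)
  expect_equal(model_coefmat_for_test(ms0$clusters[[1]]), unname(C_true),
               tolerance = 1e-8)

  # Replicating every participant leaves the estimates unchanged.
  dp_dup <- manual_design(rbind(Y, Y), rbind(X, X),
                          c(dp$row_participant,
                            sub("P", "Q", dp$row_participant)), 1, 2)
  ms_dup <- m_step(dp_dup, matrix(1, 24, 1), lags = 2, min_members = 1)
  expect_equal(ms_dup$clusters[[1]]$A, ms$clusters[[1]]$A, tolerance = 1e-10)
  expect_equal(ms_dup$clusters[[1]]$Sigma, ms$clusters[[1]]$Sigma,
               tolerance = 1e-10)
})

test_that("degenerate clusters are reset by inflating Sigma", {
  # Near-zero Sigma: the rule gives (almost) the all-10 matrix, which is
  # PD-projected; eigenvalue oracle on the projection.
  m <- var_cluster_model(1, list(matrix(0, 2, 2)), matrix(0, 2, 1),
                         diag(1e-6, 2))
  r <- reset_degenerate(m, 10)
  expect_lt(norm(r$Sigma - matrix(10, 2, 2), "F"), 1e-3)
  expect_gt(min(eigen(r$Sigma, symmetric = TRUE)$values), 0)

  # Identity + 10*J has eigenvalues {21, 1}: no projection needed.
  mi <- var_cluster_model(1, list(matrix(0, 2, 2)), matrix(0, 2, 1), diag(2))
  ri <- reset_degenerate(mi, 10)
  expect_equal(ri$Sigma, diag(2) + matrix(10, 2, 2))
  expect_equal(sort(eigen(ri$Sigma)$values), c(1, 21))

  # Increment 0 leaves the model unchanged.
  expect_equal(reset_degenerate(mi, 0)$Sigma, mi$Sigma)
})

test_that("parameter counts and information criteria follow the formulas", {
  mk_fit <- function(K, d, p, q) {
    m <- var_cluster_model(p, replicate(p, diag(0.1, d), simplify = FALSE),
                           matrix(0, d, q), diag(d), pi = 1 / K)
    structure(list(clusters = replicate(K, m, simplify = FALSE)),
              class = "lcvar_fit")
  }
  expect_equal(count_parameters(mk_fit(1, 1, 1, 1)), 3)
  expect_equal(count_parameters(mk_fit(2, 2, 1, 1)), 19)
  # Hand count: 3 * (14^2*3 + 14*6 + 14*15/2) + 2 = 3*777 + 2.
  expect_equal(count_parameters(mk_fit(3, 14, 3, 6)), 2333)

  ic0 <- information_criteria(-500, 0, 100)
  expect_equal(ic0$hqc, 1000 / 100)
  ic1 <- information_criteria(-500, 10, 100)
  expect_gt(ic1$hqc, ic0$hqc)
  expect_equal(ic1$aic, (1000 + 20) / 100)
  expect_error(information_criteria(-1, 1, 2), "n_rows")
})

test_that("EM is monotone, K=1 matches direct least squares, labels permute freely", {
  sp <- recovery_sim(2, n = 12)
  dp <- build_design(sp$panel, 1)
  fc <- fit_config(k_min = 1, k_max = 1, lag_min = 1, lag_max = 1,
                   min_members = 1, n_pseudo_random_starts = 1, seed = 3)
  f1 <- run_em(dp, 1, 1, matrix(1, 12, 1), fc, "single")
  expect_true(f1$converged)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))
  # K=1 oracle: plain multivariate least squares.
  C_ols <- t(solve(crossprod(dp$predictors),
                   crossprod(dp$predictors, dp$outcomes)))
  expect_equal(model_coefmat_for_test(f1$clusters[[1]]), unname(C_ols),
               tolerance = 1e-8)
  # Responsibilities are row-normalised.
  expect_lt(max(abs(rowSums(f1$responsibilities) - 1)), 1e-10)

  # K=2 on two well-separated clusters recovers the partition exactly.
  models <- recovery_models(2)[c(1, 3)]
  spec <- simulation_spec(14, models, c(0.5, 0.5), missing_rate = 0,
                          seed = 77)
  sp2 <- simulate_panel(spec)
  dp2 <- build_design(sp2$panel, 1)
  fc2 <- fit_config(k_min = 2, k_max = 2, lag_min = 1, lag_max = 1,
                    n_pseudo_random_starts = 3, seed = 5)
  f2 <- fit_grid(sp2$panel, fc2)$selected
  expect_equal(ari(f2$hard_labels[names(sp2$truth$labels)],
                   sp2$truth$labels), 1)
  expect_lt(max(abs(rowSums(f2$responsibilities) - 1)), 1e-10)

  # Label-switching invariance: permuted clusters give the same mixture
  # loglik, hence identical HQC/AIC.
  perm <- c(2, 1)
  r_perm <- e_step(dp2, f2$clusters[perm],
                   vapply(f2$clusters[perm], `[[`, numeric(1), "pi"))
  expect_equal(attr(r_perm, "loglik"), f2$loglik, tolerance = 1e-8)
  ic <- information_criteria(attr(r_perm, "loglik"), f2$n_params, f2$n_rows)
  expect_equal(ic$hqc, f2$hqc, tolerance = 1e-10)
  expect_equal(ic$aic, f2$aic, tolerance = 1e-10)
})

test_that("start strategies behave at boundaries and separate known groups", {
  models <- recovery_models(3)[c(1, 3)]
  spec <- simulation_spec(16, models, c(0.5, 0.5), missing_rate = 0,
                          seed = 31)
  sp <- simulate_panel(spec)
  dp <- build_design(sp$panel, 1)
  truth <- sp$truth$labels

  # K=1: everyone assigned to the single centre; identical under a seed.
  expect_true(all(max.col(pseudo_random_start(dp, 1, seed = 2)) == 1))
  expect_identical(pseudo_random_start(dp, 2, seed = 9),
                   pseudo_random_start(dp, 2, seed = 9))
  expect_error(pseudo_random_start(dp, 99, seed = 1), "exceeds")

  # When the two centres span the two true groups, initial assignment
  # accuracy is at least 0.9.
  groups <- design_groups_for_test(dp)
  found <- FALSE
  for (s in 1:25) {
    set.seed(s)
    centres <- sample(groups$ids, 2)
    if (length(unique(truth[centres])) == 2) {
      r <- pseudo_random_start(dp, 2, seed = s)
      assign <- max.col(r)
      centre_lab <- truth[centres]
      acc <- mean(centre_lab[assign] == truth[rownames(r)])
      expect_gte(acc, 0.9)
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # Rational start on separable dynamics matches the truth partition.
  rs <- rational_start(dp, 2, seed = 4)
  expect_equal(ari(max.col(rs), truth[rownames(rs)]), 1)

  # Identical participants: k-means is degenerate; falls back with warning.
  const <- roster_panel(6, 0)
  vals <- panel_values(const)
  vals[, 1] <- rep(c(30, 60, 40, 45, 60, 35), length.out = nrow(vals))
  vals[, 2] <- rep(c(40, 60), length.out = nrow(vals))
  flatp <- panel_set_values(const, vals)
  dpc <- build_design(flatp, 1)
  expect_warning(expect_warning(rational_start(dpc, 2, seed = 1),
                                "falling back"),
                 "rank-deficient")

  # K equal to n: every participant its own cluster.
  small_models <- recovery_models(4)[c(1, 3)]
  sp_small <- simulate_panel(simulation_spec(5, small_models, c(0.5, 0.5),
                                             missing_rate = 0, seed = 3))
  dps <- build_design(sp_small$panel, 1)
  rs_n <- suppressWarnings(rational_start(dps, 5, seed = 2))
  expect_equal(sort(unique(max.col(rs_n))), 1:5)
})

test_that("coefficient error shrinks with longer series", {
  errs <- sapply(c(14, 67), function(n_days) {
    models <- recovery_models(5)[c(1, 3)]
    spec <- simulation_spec(12, models, c(0.5, 0.5), n_days = n_days,
                            missing_rate = 0, seed = 21)
    sp <- simulate_panel(spec)
    dp <- build_design(sp$panel, 1)
    fc <- fit_config(k_min = 2, k_max = 2, lag_min = 1, lag_max = 1,
                     n_pseudo_random_starts = 2, seed = 6)
    f <- run_em(dp, 2, 1, rational_start(dp, 2, seed = 2), fc, "rs")
    errs2 <- sapply(list(1:2, 2:1), function(pm)
      sqrt(mean(unlist(lapply(1:2, function(k)
        (f$clusters[[pm[k]]]$A[[1]] - models[[k]]$A[[1]]) ^ 2)))))
    min(errs2)
  })
  expect_lt(errs[2], errs[1])
})

test_that("the grid ranks by HQC with the argmin selected", {
  sp <- recovery_sim(6, n = 14)
  fc <- fit_config(k_min = 1, k_max = 1, lag_min = 1, lag_max = 2,
                   min_members = 1, n_pseudo_random_starts = 2, seed = 9)
  g <- fit_grid(sp$panel, fc)
  expect_equal(nrow(g$summary), 2)
  expect_true(all(g$summary$hqc[1] <= g$summary$hqc))
  expect_equal(g$selected$hqc, min(g$summary$hqc))
  # Single-cell grid equals a plain VAR fit.
  fc1 <- fit_config(k_min = 1, k_max = 1, lag_min = 1, lag_max = 1,
                    min_members = 1, n_pseudo_random_starts = 1, seed = 9)
  g1 <- fit_grid(sp$panel, fc1)
  dp <- build_design(sp$panel, 1)
  C_ols <- t(solve(crossprod(dp$predictors),
                   crossprod(dp$predictors, dp$outcomes)))
  expect_equal(model_coefmat_for_test(g1$selected$clusters[[1]]),
               unname(C_ols), tolerance = 1e-8)
})
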