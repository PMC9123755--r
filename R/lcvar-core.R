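# EM estimation of a finite mixture of VAR(p) models with exogenous
# covariates. Participants are the mixture units: each participant's whole
# lagged design block is assigned to classes via posterior responsibilities.

# Participant grouping of a design pair: ids in first-appearance order and
# the row -> participant index map.
design_groups <- function(design) {
  ids <- unique(design$row_participant)
  list(ids = ids, gi = match(design$row_participant, ids))
}

# Predictor column set used by a model of lag p inside a design built at a
# lag >= p: covariate columns plus the first p lag blocks.
model_columns <- function(design, p) {
  if (p > design$lag)
    stop("model lag exceeds design lag")
  d <- ncol(design$outcomes)
  seq_len(design$n_covariate_cols + d * p)
}

# Stacked coefficient matrix [B | A1 | ... | Ap], d x (q + d*p).
model_coefmat <- function(model) {
  do.call(cbind, c(list(model$B), model$A))
}

# Split a stacked coefficient matrix back into (B, A list).
split_coefmat <- function(C, d, q, p) {
  B <- C[, seq_len(q), drop = FALSE]
  A <- lapply(seq_len(p), function(l)
    C[, q + (l - 1L) * d + seq_len(d), drop = FALSE])
  list(B = B, A = A)
}

# Per-row Gaussian conditional log-densities for one cluster model; NULL
# signals a non-invertible Sigma (callers route this to the reset path).
row_logliks <- function(design, model) {
  cols <- model_columns(design, model$lag)
  C <- model_coefmat(model)
  E <- design$outcomes - design$predictors[, cols, drop = FALSE] %*% t(C)
  U <- tryCatch(chol(model$Sigma), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  quad <- rowSums((E %*% backsolve(U, diag(ncol(E)))) ^ 2)
  -0.5 * ncol(E) * log(2 * pi) - sum(log(diag(U))) - 0.5 * quad
}

#' Conditional Gaussian log-likelihood of design rows under one VAR model
#'
#' Sums, over the supplied outcome rows, the log-density of the outcome
#' given its lagged predictors and covariates, with mean
#' `A %*% lags + B %*% covariates` and covariance `Sigma`. The first `p`
#' occasions per participant never appear as outcome rows (the likelihood is
#' conditional on them), and everything is computed in log space.
#'
#' @param design A `design_pair` from [build_design()] (typically the rows
#'   of one participant).
#' @param model A [var_cluster_model()] whose lag does not exceed the
#'   design's lag.
#' @return A finite scalar log-likelihood.
#' @export
conditional_loglik <- function(design, model) {
  ll <- row_logliks(design, model)
  if (is.null(ll)) stop("Sigma is not invertible")
  sum(ll)
}

# Participants x clusters matrix of conditional log-likelihoods; an all-NA
# column marks a cluster whose Sigma failed to factor.
loglik_matrix <- function(design, clusters, groups = design_groups(design)) {
  K <- length(clusters)
  L <- matrix(NA_real_, length(groups$ids), K,
              dimnames = list(groups$ids, NULL))
  for (k in seq_len(K)) {
    rl <- row_logliks(design, clusters[[k]])
    if (is.null(rl)) next
    L[, k] <- rowsum(rl, groups$gi)[, 1L]
  }
  L
}

#' E-step: posterior cluster responsibilities
#'
#' `responsibility(i, k)` is proportional to
#' `pi_k * exp(conditional_loglik_ik)`, normalised per participant through a
#' log-sum-exp so log-likelihood differences up to +-700 cannot overflow.
#'
#' @param design A `design_pair` covering all participants.
#' @param clusters List of [var_cluster_model()]s.
#' @param proportions Mixing proportions (positive, summing to 1).
#' @return Participants x clusters matrix of responsibilities; rows sum
#'   to 1. The mixture log-likelihood is attached as attribute `"loglik"`.
#' @export
e_step <- function(design, clusters, proportions) {
  stopifnot(length(clusters) == length(proportions))
  L <- loglik_matrix(design, clusters)
  if (anyNA(L)) stop("non-invertible Sigma in e_step; reset the cluster")
  lp <- sweep(L, 2L, log(proportions), "+")
  lse <- logsumexp_rows(lp)
  resp <- exp(lp - lse)
  attr(resp, "loglik") <- sum(lse)
  resp
}

#' M-step: responsibility-weighted VAR estimates per cluster
#'
#' Each cluster's stacked coefficients solve the responsibility-weighted
#' least-squares problem; `Sigma` is the weighted residual covariance (with
#' a 1e-8 ridge when near-singular) and each mixing proportion is the mean
#' responsibility. Clusters whose expected membership falls below
#' `min_members` are flagged degenerate for the caller's reset path.
#'
#' @param design A `design_pair`.
#' @param responsibilities Participants x clusters matrix (rows sum to 1),
#'   rows ordered as `unique(design$row_participant)`.
#' @param lags Integer vector of per-cluster lag orders (each `<=`
#'   the design's lag).
#' @param min_members Minimum expected membership per cluster (default 2).
#' @return List with `clusters`, `proportions` and logical `degenerate`
#'   flags.
#' @export
m_step <- function(design, responsibilities, lags, min_members = 2) {
  groups <- design_groups(design)
  K <- ncol(responsibilities)
  stopifnot(nrow(responsibilities) == length(groups$ids),
            length(lags) == K)
  d <- ncol(design$outcomes)
  q <- design$n_covariate_cols
  clusters <- vector("list", K)
  degenerate <- logical(K)
  for (k in seq_len(K)) {
    w <- responsibilities[groups$gi, k]
    eff <- sum(responsibilities[, k])
    degenerate[k] <- eff < min_members
    w <- pmax(w, 1e-12)
    cols <- model_columns(design, lags[k])
    X <- design$predictors[, cols, drop = FALSE]
    sw <- sqrt(w)
    Xw <- X * sw
    Yw <- design$outcomes * sw
    XtX <- crossprod(Xw)
    diag(XtX) <- diag(XtX) + 1e-10
    C <- t(solve(XtX, crossprod(Xw, Yw)))
    E <- design$outcomes - X %*% t(C)
    Sigma <- crossprod(E * sw) / sum(w)
    Sigma <- (Sigma + t(Sigma)) / 2
    ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.finite(ev_min) || ev_min < 1e-8) {
      Sigma <- Sigma + diag(1e-8, d)
      Sigma <- make_positive_definite(Sigma)
      degenerate[k] <- TRUE
    }
    parts <- split_coefmat(C, d, q, lags[k])
    clusters[[k]] <- var_cluster_model(lags[k], parts$A, parts$B, Sigma,
                                       pi = max(1e-12, mean(responsibilities[, k])))
  }
  props <- colMeans(responsibilities)
  props <- props / sum(props)
  for (k in seq_len(K)) clusters[[k]]$pi <- props[k]
  list(clusters = clusters, proportions = props, degenerate = degenerate)
}

#' Reset a degenerate cluster's innovation covariance
#'
#' Applies the degeneracy recovery rule: every element of `Sigma` is
#' increased by `increment`, then the matrix is symmetrised and projected to
#' the nearest positive definite matrix if needed. Callers pair this with a
#' uniform redraw of the affected cluster's responsibilities (see
#' [run_em()]).
#'
#' @param model A flagged [var_cluster_model()].
#' @param increment Added to every element of `Sigma` (default 10).
#' @return The model with the inflated covariance.
#' @export
reset_degenerate <- function(model, increment = 10) {
  model$Sigma <- make_positive_definite(model$Sigma + increment, floor = 1e-6)
  model
}

#' Free-parameter count of a mixture fit
#'
#' `sum_k [d^2 p_k + d q + d(d+1)/2] + (K - 1)` where `q` counts covariate
#' columns including the intercept.
#'
#' @param fit An `lcvar_fit` from [run_em()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(fit) {
  n_lcvar_params(vapply(fit$clusters, `[[`, integer(1), "lag"),
                 d = nrow(fit$clusters[[1L]]$Sigma),
                 q = ncol(fit$clusters[[1L]]$B),
                 K = length(fit$clusters))
}

n_lcvar_params <- function(lags, d, q, K) {
  as.integer(sum(d ^ 2 * lags + d * q + d * (d + 1) / 2) + (K - 1))
}

#' Information criteria for a mixture fit
#'
#' `HQC = (-2 loglik + 2 q ln(ln N)) / N` and
#' `AIC = (-2 loglik + 2 q) / N`, with `q` the free-parameter count and `N`
#' the number of modeled outcome rows. Lower is better.
#'
#' @param loglik Mixture log-likelihood.
#' @param n_params Free-parameter count (see [count_parameters()]).
#' @param n_rows Total modeled outcome rows; must exceed `e` for
#'   `ln(ln(N))` to exist.
#' @return List with elements `hqc` and `aic`.
#' @export
information_criteria <- function(loglik, n_params, n_rows) {
  if (!is.finite(loglik)) stop("log-likelihood must be finite")
  if (n_rows <= exp(1))
    stop("information criteria undefined for n_rows <= e")
  list(hqc = (-2 * loglik + 2 * n_params * log(log(n_rows))) / n_rows,
       aic = (-2 * loglik + 2 * n_params) / n_rows)
}

#' Estimation hyperparameters
#'
#' Defaults follow the standard protocol for this analysis: clusters 2-3,
#' lags 1-3, at least two members per cluster, 15 pseudo-random starts plus
#' a rational (k-means) start, 50 EM iterations per start, log-likelihood
#' tolerance 1e-07, and a covariance reset increment of 10.
#'
#' @param k_min,k_max Cluster-count grid (defaults 2 and 3).
#' @param lag_min,lag_max Lag grid (defaults 1 and 3).
#' @param min_members Minimum members per cluster (default 2).
#' @param n_pseudo_random_starts Pseudo-random starts per grid cell
#'   (default 15).
#' @param use_rational_start Add the k-means start? Default `TRUE`.
#' @param max_em_iterations EM iterations allowed per start (default 50).
#' @param loglik_tol Convergence tolerance on the log-likelihood change
#'   (default 1e-07).
#' @param sigma_reset_increment Added to every `Sigma` element on reset
#'   (default 10).
#' @param heterogeneous_lags Also search non-decreasing per-cluster lag
#'   vectors? Default `FALSE` (homogeneous lags).
#' @param seed Master seed; all start-level randomness is derived from it.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(k_min = 2, k_max = 3, lag_min = 1, lag_max = 3,
                       min_members = 2, n_pseudo_random_starts = 15,
                       use_rational_start = TRUE, max_em_iterations = 50,
                       loglik_tol = 1e-07, sigma_reset_increment = 10,
                       heterogeneous_lags = FALSE, seed = 1) {
  stopifnot(is_count(k_min), k_min >= 1, is_count(k_max), k_max >= k_min,
            is_count(lag_min), lag_min >= 1, is_count(lag_max),
            lag_max >= lag_min, is_count(min_members),
            is_count(n_pseudo_random_starts),
            is_count(max_em_iterations), max_em_iterations >= 1,
            loglik_tol > 0, sigma_reset_increment >= 0)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 lag_min = as.integer(lag_min), lag_max = as.integer(lag_max),
                 min_members = as.integer(min_members),
                 n_pseudo_random_starts = as.integer(n_pseudo_random_starts),
                 use_rational_start = isTRUE(use_rational_start),
                 max_em_iterations = as.integer(max_em_iterations),
                 loglik_tol = loglik_tol,
                 sigma_reset_increment = sigma_reset_increment,
                 heterogeneous_lags = isTRUE(heterogeneous_lags),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Ridge-stabilised per-participant VAR fit used by the start strategies.
fit_single_var <- function(Y, X, ridge = 1e-6) {
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + ridge * (1 + mean(diag(XtX)))
  C <- t(solve(XtX, crossprod(X, Y)))
  E <- Y - X %*% t(C)
  Sigma <- make_positive_definite(crossprod(E) / nrow(E), floor = 1e-4)
  list(C = C, Sigma = Sigma)
}

#' Pseudo-random start: k participants as cluster centres
#'
#' Draws `K` distinct participants, fits each one's own (ridge-stabilised)
#' VAR, assigns every participant to the centre whose model gives it the
#' highest conditional likelihood, and returns the one-hot assignment
#' softened by 1e-3.
#'
#' @param design A `design_pair`.
#' @param K Number of clusters (`<=` number of participants).
#' @param seed Integer seed.
#' @param lags Per-cluster lag orders (default: the design lag for all).
#' @return Participants x K responsibility matrix.
#' @export
pseudo_random_start <- function(design, K, seed = 1,
                                lags = rep(design$lag, K)) {
  groups <- design_groups(design)
  n <- length(groups$ids)
  if (K > n) stop("K exceeds the number of participants")
  set.seed(as.integer(seed))
  centres <- sample(groups$ids, K)
  d <- ncol(design$outcomes)
  q <- design$n_covariate_cols
  models <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- design$row_participant == centres[k]
    cols <- model_columns(design, lags[k])
    fit <- fit_single_var(design$outcomes[rows, , drop = FALSE],
                          design$predictors[rows, cols, drop = FALSE])
    parts <- split_coefmat(fit$C, d, q, lags[k])
    models[[k]] <- var_cluster_model(lags[k], parts$A, parts$B, fit$Sigma,
                                     pi = 1 / K)
  }
  L <- loglik_matrix(design, models, groups)
  assign <- max.col(L, ties.method = "first")
  eps <- 1e-3
  resp <- matrix(eps, n, K, dimnames = list(groups$ids, NULL))
  resp[cbind(seq_len(n), assign)] <- 1 - eps * (K - 1)
  resp
}

#' Rational start: k-means on per-participant VAR coefficients
#'
#' Fits every participant's own VAR-plus-covariate coefficient vector
#' (ridge-stabilised, with a warning on rank deficiency) and partitions the
#' vectors by k-means with 10 restarts under a fixed seed. Degenerate input
#' (all participants essentially identical) falls back to
#' [pseudo_random_start()] with a warning.
#'
#' @inheritParams pseudo_random_start
#' @return Participants x K one-hot responsibility matrix.
#' @export
rational_start <- function(design, K, seed = 1) {
  groups <- design_groups(design)
  n <- length(groups$ids)
  if (K > n) stop("K exceeds the number of participants")
  p_cols <- ncol(design$predictors)
  feats <- matrix(0, n, ncol(design$outcomes) * p_cols)
  rank_warn <- FALSE
  for (i in seq_len(n)) {
    rows <- design$row_participant == groups$ids[i]
    X <- design$predictors[rows, , drop = FALSE]
    if (qr(X)$rank < ncol(X)) rank_warn <- TRUE
    feats[i, ] <- as.numeric(fit_single_var(
      design$outcomes[rows, , drop = FALSE], X)$C)
  }
  if (rank_warn)
    warning("rank-deficient individual VAR(s); ridge-stabilised fits used")
  if (max(apply(feats, 2L, stats::sd)) < 1e-10) {
    warning("identical individual coefficients; falling back to a pseudo-random start")
    return(pseudo_random_start(design, K, seed))
  }
  set.seed(as.integer(seed))
  km <- tryCatch(stats::kmeans(feats, centers = K, nstart = 10),
                 error = function(e) NULL)
  if (is.null(km)) {
    warning("k-means failed on individual coefficients; falling back to a pseudo-random start")
    return(pseudo_random_start(design, K, seed))
  }
  resp <- matrix(0, n, K, dimnames = list(groups$ids, NULL))
  resp[cbind(seq_len(n), km$cluster)] <- 1
  resp
}

#' Run the EM algorithm from one start
#'
#' Alternates [m_step()] and [e_step()] until the log-likelihood changes by
#' less than `config$loglik_tol` or `config$max_em_iterations` is reached.
#' When a cluster degenerates (expected membership below
#' `config$min_members`, hard-label count below it, or a non-PD `Sigma`),
#' the cluster's covariance is inflated by [reset_degenerate()] and its
#' responsibilities are re-drawn uniformly; the event is counted and the
#' monotone-likelihood guarantee restarts after it.
#'
#' @param design A `design_pair` covering all participants.
#' @param K Number of clusters.
#' @param lags Per-cluster lag vector (recycled if scalar).
#' @param start Initial responsibilities (participants x K).
#' @param config A [fit_config()].
#' @param start_descriptor Provenance string stored in the fit.
#' @return An object of class `lcvar_fit`: `clusters`, `responsibilities`,
#'   `hard_labels`, `loglik`, `loglik_trace`, `hqc`, `aic`, `n_params`,
#'   `converged`, `n_resets`, `start_descriptor`, and `ok` (whether every
#'   cluster kept at least `min_members` hard members).
#' @export
run_em <- function(design, K, lags, start, config = fit_config(),
                   start_descriptor = "unspecified") {
  lags <- as.integer(rep(lags, length.out = K))
  groups <- design_groups(design)
  n <- length(groups$ids)
  stopifnot(nrow(start) == n, ncol(start) == K)
  resp <- start / rowSums(start)
  seed_stream <- derive_seed(config$seed, 991L)
  max_resets <- 10L
  n_resets <- 0L
  reset_iters <- integer(0)
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  clusters <- NULL
  proportions <- rep(1 / K, K)
  ll <- -Inf

  for (iter in seq_len(config$max_em_iterations)) {
    ms <- m_step(design, resp, lags, min_members = config$min_members)
    clusters <- ms$clusters
    proportions <- ms$proportions
    L <- loglik_matrix(design, clusters, groups)
    bad <- ms$degenerate | apply(L, 2L, anyNA)
    if (!any(bad)) {
      lp <- sweep(L, 2L, log(proportions), "+")
      lse <- logsumexp_rows(lp)
      ll <- sum(lse)
      resp_new <- exp(lp - lse)
      counts <- tabulate(max.col(resp_new, ties.method = "first"), K)
      bad <- counts < config$min_members
    }
    if (any(bad)) {
      if (n_resets >= max_resets) { converged <- FALSE; break }
      set.seed(derive_seed(seed_stream, n_resets + 1L))
      for (k in which(bad)) {
        clusters[[k]] <- reset_degenerate(clusters[[k]],
                                          config$sigma_reset_increment)
        resp[, k] <- stats::runif(n)
      }
      resp <- resp / rowSums(resp)
      n_resets <- n_resets + 1L
      reset_iters <- c(reset_iters, iter)
      prev_ll <- -Inf
      next
    }
    trace <- c(trace, ll)
    if (is.finite(prev_ll) && abs(ll - prev_ll) < config$loglik_tol) {
      converged <- TRUE
      resp <- resp_new
      break
    }
    prev_ll <- ll
    resp <- resp_new
  }

  hard <- max.col(resp, ties.method = "first")
  counts <- tabulate(hard, K)
  n_params <- n_lcvar_params(lags, d = ncol(design$outcomes),
                             q = design$n_covariate_cols, K = K)
  ic <- if (is.finite(ll))
    information_criteria(ll, n_params, nrow(design$outcomes))
  else list(hqc = NA_real_, aic = NA_real_)
  structure(list(clusters = clusters,
                 responsibilities = resp,
                 hard_labels = stats::setNames(hard, groups$ids),
                 loglik = ll, loglik_trace = trace,
                 hqc = ic$hqc, aic = ic$aic, n_params = n_params,
                 converged = converged, n_resets = n_resets,
                 reset_iterations = reset_iters,
                 start_descriptor = start_descriptor,
                 n_rows = nrow(design$outcomes),
                 lags = lags,
                 variable_names = design$variable_names,
                 ok = is.finite(ll) && all(counts >= config$min_members)),
            class = "lcvar_fit")
}

#' @export
print.lcvar_fit <- function(x, ...) {
  cat(sprintf(
    "LCVAR fit: K = %d (lags %s), loglik %.3f, HQC %.4f, %sconverged, %d reset(s)\n",
    length(x$clusters), paste(x$lags, collapse = ","), x$loglik, x$hqc,
    if (x$converged) "" else "NOT ", x$n_resets))
  cat("  cluster sizes:", paste(tabulate(x$hard_labels, length(x$clusters)),
                                collapse = ", "), "\n")
  invisible(x)
}

# Lag combinations for one K: homogeneous vectors by default, all
# non-decreasing per-cluster vectors when heterogeneous lags are on
# (canonicalised ascending, so label permutations do not duplicate cells).
lag_combinations <- function(K, lag_min, lag_max, heterogeneous) {
  if (!heterogeneous)
    return(lapply(lag_min:lag_max, function(p) rep(p, K)))
  grid <- do.call(expand.grid, rep(list(lag_min:lag_max), K))
  keep <- apply(grid, 1L, function(v) all(diff(v) >= 0))
  lapply(which(keep), function(r) as.integer(grid[r, ]))
}

#' Fit the full cluster-count by lag grid
#'
#' For every `K` in `[k_min, k_max]` and every lag combination, runs all
#' starts (the configured pseudo-random starts, the rational k-means start,
#' and a warm start from the best previous fit with the same `K`), keeps the
#' best-log-likelihood valid fit per cell — preferring converged fits — and
#' ranks cells by HQC. Ties break toward fewer parameters, then smaller `K`,
#' then lower lag.
#'
#' @param panel A fully observed [ema_panel()] (standardized or raw).
#' @param config A [fit_config()].
#' @param covariates,trend Passed to [build_design()].
#' @return An object of class `lcvar_grid`: `summary` (one ranked row per
#'   cell), `fits` (per-cell best fits, named `K<k>_p<lags>`), and
#'   `selected` (the HQC argmin).
#' @export
fit_grid <- function(panel, config = fit_config(), covariates = "beep",
                     trend = FALSE) {
  stopifnot(inherits(config, "fit_config"))
  designs <- list()
  for (p in config$lag_min:config$lag_max)
    designs[[p]] <- build_design(panel, p, covariates = covariates,
                                 trend = trend)

  cells <- list()
  for (K in config$k_min:config$k_max)
    for (lags in lag_combinations(K, config$lag_min, config$lag_max,
                                  config$heterogeneous_lags))
      cells[[length(cells) + 1L]] <- list(K = K, lags = lags)

  fits <- list()
  rows <- list()
  warm <- list()  # best responsibilities per K so far
  for (ci in seq_along(cells)) {
    K <- cells[[ci]]$K
    lags <- cells[[ci]]$lags
    pmax_ <- max(lags)
    dp <- designs[[pmax_]]
    cell_id <- sprintf("K%d_p%s", K, paste(lags, collapse = ""))

    starts <- list()
    if (config$use_rational_start) {
      rs <- withCallingHandlers(
        rational_start(dp, K, seed = derive_seed(config$seed, ci)),
        warning = function(w) invokeRestart("muffleWarning"))
      starts[[length(starts) + 1L]] <- list(resp = rs, desc = "rational")
    }
    for (s in seq_len(config$n_pseudo_random_starts)) {
      pr <- pseudo_random_start(dp, K,
                                seed = derive_seed(config$seed,
                                                   ci * 1000L + s),
                                lags = lags)
      starts[[length(starts) + 1L]] <- list(resp = pr,
                                            desc = sprintf("pseudo-random %d", s))
    }
    if (!is.null(warm[[as.character(K)]]))
      starts[[length(starts) + 1L]] <- list(resp = warm[[as.character(K)]],
                                            desc = "warm")

    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        run_em(dp, K, lags, st$resp, config, start_descriptor = st$desc),
        error = function(e) NULL)
      if (is.null(fit) || !fit$ok) next
      better <- is.null(best) ||
        (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$loglik > best$loglik)
      if (better) best <- fit
    }
    if (is.null(best)) {
      rows[[ci]] <- data.frame(cell = cell_id, K = K,
                               lags = paste(lags, collapse = ","),
                               loglik = NA_real_, n_params = NA_integer_,
                               hqc = NA_real_, aic = NA_real_,
                               converged = NA, n_resets = NA_integer_,
                               start = NA_character_)
      next
    }
    fits[[cell_id]] <- best
    warm[[as.character(K)]] <- best$responsibilities
    rows[[ci]] <- data.frame(cell = cell_id, K = K,
                             lags = paste(lags, collapse = ","),
                             loglik = best$loglik, n_params = best$n_params,
                             hqc = best$hqc, aic = best$aic,
                             converged = best$converged,
                             n_resets = best$n_resets,
                             start = best$start_descriptor)
  }
  summary <- do.call(rbind, rows)
  ok <- which(!is.na(summary$hqc))
  if (length(ok) == 0L) stop("every grid cell failed")
  ord <- ok[order(summary$hqc[ok], summary$n_params[ok], summary$K[ok],
                  summary$lags[ok])]
  summary <- rbind(summary[ord, , drop = FALSE],
                   summary[setdiff(seq_len(nrow(summary)), ord), ,
                           drop = FALSE])
  rownames(summary) <- NULL
  structure(list(summary = summary, fits = fits,
                 selected = fits[[summary$cell[1L]]], config = config),
            class = "lcvar_grid")
}

#' @export
print.lcvar_grid <- function(x, ...) {
  cat("LCVAR grid (ranked by HQC):\n")
  print(x$summary[, c("cell", "K", "lags", "loglik", "n_params", "hqc",
                      "converged", "n_resets")], row.names = FALSE)
  cat("selected:", x$summary$cell[1L], "\n")
  invisible(x)
}
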