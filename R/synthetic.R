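#' Generate stable VAR parameters for simulation
#'
#' Builds a cluster model whose lag-1 diagonal holds moderate autoregressive
#' inertia, with designated cross-lagged entries (e.g. craving -> calm) set
#' to `+-cross_effect` before a final rescaling step that enforces the
#' spectral-radius cap. Higher lags decay geometrically. The innovation
#' covariance is `innovation_sd^2 * I`, positive definite by construction.
#'
#' @param n_vars Number of endogenous variables (>= 1).
#' @param lag Lag order (>= 1).
#' @param cross_effect Signed magnitude written into the designated
#'   cross-lagged entries (default 0.2).
#' @param spectral_cap Upper bound in (0, 1) for the companion spectral
#'   radius (default 0.9).
#' @param seed Integer seed for the random diagonal draw.
#' @param cross_entries Integer matrix with columns (outcome, predictor, lag)
#'   naming the entries that receive `cross_effect`; default is the single
#'   entry (2, 1, 1) when `n_vars >= 2`.
#' @param diag_base Center of the uniform draw for lag-1 diagonal entries
#'   (default 0.3, spread +-0.1).
#' @param innovation_sd Innovation standard deviation on the 0-100 slider
#'   scale (default 5; see the methods vignette for the calibration).
#' @return A [var_cluster_model()] with companion spectral radius
#'   `<= spectral_cap`.
#' @export
make_var_params <- function(n_vars, lag, cross_effect = 0.2,
                            spectral_cap = 0.9, seed = 1,
                            cross_entries = NULL, diag_base = 0.3,
                            innovation_sd = 5) {
  stopifnot(is_count(n_vars), n_vars >= 1, is_count(lag), lag >= 1,
            spectral_cap > 0, spectral_cap < 1)
  set.seed(as.integer(seed))
  A <- lapply(seq_len(lag), function(l) {
    diag(stats::runif(n_vars, diag_base - 0.1, diag_base + 0.1) *
           0.5 ^ (l - 1), nrow = n_vars)
  })
  if (is.null(cross_entries) && n_vars >= 2L)
    cross_entries <- matrix(c(2L, 1L, 1L), 1L)
  if (!is.null(cross_entries)) {
    cross_entries <- matrix(as.integer(cross_entries), ncol = 3L)
    for (r in seq_len(nrow(cross_entries))) {
      e <- cross_entries[r, ]
      if (e[3L] > lag) stop("cross entry at lag beyond model lag")
      A[[e[3L]]][e[1L], e[2L]] <- cross_effect
    }
  }
  rho <- spectral_radius(A)
  attempts <- 0L
  while (rho > spectral_cap && attempts < 25L) {
    s <- 0.98 * spectral_cap / rho
    A <- lapply(A, function(a) a * s)
    rho <- spectral_radius(A)
    attempts <- attempts + 1L
  }
  if (rho > spectral_cap)
    stop(sprintf("could not stabilise VAR: spectral radius %.4f exceeds cap %.2f",
                 rho, spectral_cap))
  var_cluster_model(lag, A, B = matrix(0, n_vars, 1L),
                    Sigma = diag(innovation_sd ^ 2, n_vars))
}

#' Flat and M-shaped diurnal mean profiles
#'
#' `flat_profile()` gives every beep and variable the same mean.
#' `mcurve_profile()` overlays, on selected variables, the characteristic
#' two-peak daytime course of hunger/craving (high mid-morning and late
#' afternoon, lower at mid-day and in the evening).
#'
#' @param beeps_per_day Number of daily beeps.
#' @param n_vars Number of variables.
#' @param level Baseline mean on the 0-100 scale (default 50).
#' @return A `beeps_per_day x n_vars` matrix of means.
#' @export
flat_profile <- function(beeps_per_day = 6, n_vars = 14, level = 50) {
  matrix(level, beeps_per_day, n_vars)
}

#' @rdname flat_profile
#' @param mcurve_vars Column indices receiving the M-shaped course.
#' @param amplitude Peak height above baseline (default 12).
#' @export
mcurve_profile <- function(beeps_per_day = 6, n_vars = 14,
                           mcurve_vars = n_vars - c(1L, 0L),
                           level = 50, amplitude = 12) {
  prof <- flat_profile(beeps_per_day, n_vars, level)
  # Two-peak shape over the day: rise to mid-morning, dip, rise again late
  # afternoon, fall in the evening.
  shape <- c(0, 1, 0.25, 0.35, 1, 0.15)
  if (beeps_per_day != 6L)
    shape <- stats::approx(seq(0, 1, length.out = 6L), shape,
                           seq(0, 1, length.out = beeps_per_day))$y
  for (v in mcurve_vars)
    prof[, v] <- level - amplitude / 2 + amplitude * shape
  prof
}

#' Specification of a synthetic EMA study
#'
#' Collects everything [simulate_panel()] needs: the sampling design
#' (participants, days, beeps), per-cluster VAR dynamics, per-cluster
#' diurnal mean profiles, the missingness mechanism and the seed. Optional
#' `trait_means` / `gender_probs` feed [simulate_traits()] through the
#' returned ground truth.
#'
#' @param n_participants Number of participants.
#' @param cluster_models List of [var_cluster_model()]s, one per cluster.
#' @param cluster_proportions Probability vector over clusters (sums to 1,
#'   all entries > 0).
#' @param n_days,beeps_per_day Study schedule (defaults 14 and 6).
#' @param diurnal_profiles List (per cluster) of `beeps x n_vars` mean
#'   matrices; default: flat 50 for every cluster.
#' @param missing_rate Probability that an individual observation is masked
#'   missing. A scalar gives MCAR; a vector of length `beeps_per_day` gives
#'   a beep-dependent (MAR) mechanism. Default 0.1.
#' @param dropout_rule Optional `function(n)` returning per-participant
#'   completed-prompt counts; the remaining prompts are masked whole.
#' @param trait_means Optional cluster x trait matrix for [simulate_traits()].
#' @param gender_probs Optional cluster x 2 matrix of (female, male)
#'   probabilities.
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_participants, cluster_models,
                            cluster_proportions,
                            n_days = 14, beeps_per_day = 6,
                            diurnal_profiles = NULL,
                            missing_rate = 0.1, dropout_rule = NULL,
                            trait_means = NULL, gender_probs = NULL,
                            seed = 1) {
  stopifnot(is_count(n_participants), n_participants >= 1,
            is.list(cluster_models), length(cluster_models) >= 1,
            is_count(n_days), is_count(beeps_per_day))
  K <- length(cluster_models)
  if (length(cluster_proportions) != K)
    stop("cluster_proportions length must match cluster_models")
  if (abs(sum(cluster_proportions) - 1) > 1e-12 || any(cluster_proportions <= 0))
    stop("cluster_proportions must be positive and sum to 1")
  if (any(missing_rate < 0) || any(missing_rate >= 1))
    stop("missing_rate must lie in [0, 1)")
  if (!length(missing_rate) %in% c(1L, beeps_per_day))
    stop("missing_rate must be scalar or one value per beep")
  n_vars <- nrow(cluster_models[[1L]]$Sigma)
  for (k in seq_len(K)) {
    if (nrow(cluster_models[[k]]$Sigma) != n_vars)
      stop("all cluster models must share n_vars")
    rho <- spectral_radius(cluster_models[[k]])
    if (rho >= 1)
      stop(sprintf("cluster %d is unstable (spectral radius %.3f)", k, rho))
  }
  if (is.null(diurnal_profiles))
    diurnal_profiles <- replicate(K, flat_profile(beeps_per_day, n_vars),
                                  simplify = FALSE)
  for (k in seq_len(K))
    stopifnot(all(dim(diurnal_profiles[[k]]) == c(beeps_per_day, n_vars)))
  if (!is.null(trait_means)) trait_means <- as.matrix(trait_means)
  if (!is.null(gender_probs)) {
    gender_probs <- as.matrix(gender_probs)
    stopifnot(nrow(gender_probs) == K, ncol(gender_probs) == 2L,
              all(abs(rowSums(gender_probs) - 1) < 1e-8))
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 beeps_per_day = as.integer(beeps_per_day),
                 n_vars = n_vars, cluster_models = cluster_models,
                 cluster_proportions = cluster_proportions,
                 diurnal_profiles = diurnal_profiles,
                 missing_rate = missing_rate, dropout_rule = dropout_rule,
                 trait_means = trait_means, gender_probs = gender_probs,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an EMA panel with known cluster structure
#'
#' Each participant is assigned a cluster by sampling the mixing
#' proportions (resampled, up to a bound, until every cluster has at least
#' two members whenever the roster allows it). Series are generated from the
#' cluster's VAR recursion on deviations, after a 50-step burn-in, then the
#' beep-specific diurnal mean is added and values are clamped to [0, 100].
#' Observations are masked missing by the configured mechanism; masked
#' records are flagged `NA`, never dropped, so record counts always equal
#' `n_participants * n_days * beeps_per_day`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `panel` (an [ema_panel()]) and `truth` (labels plus the
#'   trait/gender ground truth carried over from the spec).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  K <- length(spec$cluster_models)
  d <- spec$n_vars
  B <- spec$beeps_per_day
  Tt <- spec$n_days * B
  burn <- 50L

  labels <- sample.int(K, n, replace = TRUE, prob = spec$cluster_proportions)
  if (n >= 2L * K) {
    tries <- 0L
    while (min(tabulate(labels, K)) < 2L && tries < 100L) {
      labels <- sample.int(K, n, replace = TRUE,
                           prob = spec$cluster_proportions)
      tries <- tries + 1L
    }
    if (min(tabulate(labels, K)) < 2L)
      stop("could not allocate at least two members per cluster")
  }

  ids <- sprintf("P%03d", seq_len(n))
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    m <- spec$cluster_models[[labels[i]]]
    p <- m$lag
    chol_S <- chol(m$Sigma)
    total <- burn + Tt
    dev <- matrix(0, total + p, d)
    eps <- matrix(stats::rnorm(total * d), total, d) %*% chol_S
    for (t in seq_len(total)) {
      x <- eps[t, ]
      for (l in seq_len(p)) x <- x + m$A[[l]] %*% dev[t + p - l, ]
      dev[t + p, ] <- x
    }
    dev <- dev[(p + burn + 1L):(p + total), , drop = FALSE]
    beeps <- rep(seq_len(B), spec$n_days)
    days <- rep(seq_len(spec$n_days), each = B)
    vals <- spec$diurnal_profiles[[labels[i]]][beeps, , drop = FALSE] + dev
    vals <- pmin(pmax(vals, 0), 100)

    if (!is.null(spec$dropout_rule)) {
      completed <- min(Tt, max(0L, as.integer(spec$dropout_rule(1L))))
      if (completed < Tt)
        vals[sample.int(Tt, Tt - completed), ] <- NA_real_
    }
    rate <- if (length(spec$missing_rate) == 1L)
      rep(spec$missing_rate, B) else spec$missing_rate
    if (any(rate > 0)) {
      mask <- matrix(stats::runif(Tt * d) < rate[beeps], Tt, d)
      vals[mask] <- NA_real_
    }
    df <- data.frame(participant_id = ids[i], day = days, beep = beeps,
                     clock_time = default_beep_times(B)[beeps])
    rec_list[[i]] <- cbind(df, as.data.frame(vals))
  }
  records <- do.call(rbind, rec_list)
  vn <- if (d == 14L) ema_variable_names() else paste0("item_", seq_len(d))
  names(records)[-(1:4)] <- vn
  panel <- ema_panel(records,
                     list(n_days = spec$n_days, beeps_per_day = B,
                          beep_times = default_beep_times(B)),
                     vn)
  truth <- list(labels = stats::setNames(labels, ids),
                trait_means = spec$trait_means,
                gender_probs = spec$gender_probs)
  list(panel = panel, truth = truth)
}

# Beep clock times in minutes; the canonical six-beep day, or an evenly
# spaced day for other beep counts.
default_beep_times <- function(beeps_per_day) {
  if (beeps_per_day == 6L) return(c(540, 690, 840, 990, 1140, 1290))
  round(seq(540, 1290, length.out = beeps_per_day))
}

#' Simulate a between-subject trait table
#'
#' One row per participant: cluster mean plus Gaussian noise for each trait,
#' and a gender category drawn from the cluster's gender probabilities.
#'
#' @param truth Ground-truth list from [simulate_panel()]; must carry
#'   `trait_means` (cluster x trait) and, optionally, `gender_probs`.
#' @param noise_sd Trait noise standard deviation (scalar or one per trait).
#' @param seed Integer seed.
#' @return Data frame: `participant_id`, `cluster`, one column per trait,
#'   and `gender` when `gender_probs` is available.
#' @export
simulate_traits <- function(truth, noise_sd = 1, seed = 1) {
  if (is.null(truth$trait_means))
    stop("truth carries no trait_means")
  labels <- truth$labels
  K <- nrow(truth$trait_means)
  if (any(!labels %in% seq_len(K)))
    stop("unknown cluster label in truth$labels")
  set.seed(as.integer(seed))
  n <- length(labels)
  nt <- ncol(truth$trait_means)
  sds <- rep(noise_sd, length.out = nt)
  traits <- truth$trait_means[labels, , drop = FALSE] +
    sweep(matrix(stats::rnorm(n * nt), n, nt), 2L, sds, "*")
  tn <- colnames(truth$trait_means) %||% paste0("trait_", seq_len(nt))
  colnames(traits) <- tn
  out <- data.frame(participant_id = names(labels),
                    cluster = as.integer(labels))
  out <- cbind(out, as.data.frame(traits))
  if (!is.null(truth$gender_probs)) {
    out$gender <- factor(vapply(labels, function(k) {
      sample(c("female", "male"), 1L, prob = truth$gender_probs[k, ])
    }, character(1)), levels = c("female", "male"))
  }
  rownames(out) <- NULL
  out
}

#' Temporally shuffle a panel (null control)
#'
#' Within each participant and variable, the observation order is randomly
#' permuted. This destroys lagged temporal structure while preserving every
#' participant-by-variable marginal distribution exactly, giving a
#' randomized-data control: a correctly behaving model fitted to the result
#' should find lagged coefficients near zero.
#'
#' @param panel An [ema_panel()] with at least one record.
#' @param seed Integer seed.
#' @return The shuffled [ema_panel()].
#' @export
shuffle_null <- function(panel, seed = 1) {
  if (nrow(panel$records) == 0L) stop("panel is empty")
  set.seed(as.integer(seed))
  vals <- panel_values(panel)
  for (id in panel_participants(panel)) {
    rows <- which(panel$records$participant_id == id)
    if (length(rows) < 2L) next
    for (j in seq_len(ncol(vals)))
      vals[rows, j] <- vals[sample(rows), j]
  }
  panel_set_values(panel, vals)
}
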