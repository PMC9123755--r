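# Shared fixture builders. Everything is generated in code at test time.

# The three-cluster recovery study: clusters differ in two designated
# cross-lagged entries, (2,1) and (4,3) at lag 1, with effects +0.5 / 0 /
# -0.5 (adjacent separation 0.5).
recovery_cross_entries <- rbind(c(2L, 1L, 1L), c(4L, 3L, 1L))

recovery_models <- function(s) {
  eff <- c(0.5, 0, -0.5)
  lapply(1:3, function(k)
    make_var_params(4, 1, cross_effect = eff[k], seed = s * 10 + k,
                    cross_entries = recovery_cross_entries))
}

recovery_sim <- function(s, n = 60, missing_rate = 0) {
  models <- recovery_models(s)
  spec <- simulation_spec(n, models, c(0.4, 0.35, 0.25),
                          missing_rate = missing_rate, seed = 100 + s)
  c(simulate_panel(spec), list(models = models))
}

# Max-abs lag-coefficient error after aligning fitted clusters to the truth
# by the best label permutation.
perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

coef_error <- function(fit, models) {
  errs <- vapply(perms3, function(pm) {
    max(vapply(seq_along(models), function(k)
      max(abs(fit$clusters[[pm[k]]]$A[[1]] - models[[k]]$A[[1]])),
      numeric(1)))
  }, numeric(1))
  min(errs)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A deterministic roster panel: `n_total` participants on the 14x6 schedule,
# of whom `n_low` completed only `low_completed` prompts (the rest answered
# everything). Values are constant 50; unanswered prompts are NA records.
roster_panel <- function(n_total = 136, n_low = 21, low_completed = 49) {
  D <- 14L; B <- 6L
  ids <- sprintf("R%03d", seq_len(n_total))
  base <- expand.grid(beep = seq_len(B), day = seq_len(D))
  records <- do.call(rbind, lapply(seq_along(ids), function(i) {
    df <- data.frame(participant_id = ids[i], day = base$day,
                     beep = base$beep,
                     clock_time = c(540, 690, 840, 990, 1140, 1290)[base$beep],
                     item_1 = 50, item_2 = 50)
    if (i <= n_low) {
      miss <- seq_len(D * B) > low_completed
      df$item_1[miss] <- NA_real_
    }
    df
  }))
  ema_panel(records, default_schedule(14))
}

# Minimal single-participant panel holding a given univariate series.
series_panel <- function(values, beeps_per_day = length(values)) {
  n <- length(values)
  days <- rep(seq_len(ceiling(n / beeps_per_day)), each = beeps_per_day)[1:n]
  beeps <- rep(seq_len(beeps_per_day), length.out = n)
  rec <- data.frame(participant_id = "P1", day = days, beep = beeps,
                    clock_time = beeps * 100, y = values)
  ema_panel(rec, list(n_days = max(days), beeps_per_day = beeps_per_day,
                      beep_times = seq_len(beeps_per_day) * 100))
}

# Hand-built design pair for direct unit tests of the estimation steps.
manual_design <- function(outcomes, predictors, row_participant,
                          n_covariate_cols, lag) {
  structure(list(outcomes = outcomes, predictors = predictors,
                 row_participant = row_participant, lag = as.integer(lag),
                 n_covariate_cols = as.integer(n_covariate_cols),
                 variable_names = colnames(outcomes)),
            class = "design_pair")
}

# Access to internal helpers used by oracle comparisons.
model_coefmat_for_test <- function(m) unname(lcvar:::model_coefmat(m))
design_groups_for_test <- function(dp) lcvar:::design_groups(dp)
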