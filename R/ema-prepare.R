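#' Per-participant compliance
#'
#' A prompt counts as completed only when every item was answered (the app
#' expired whole questionnaires, so partially answered prompts are treated
#' as not completed). The denominator is the scheduled number of prompts,
#' `n_days * beeps_per_day`, regardless of how many records are present.
#'
#' @param panel An [ema_panel()].
#' @return Named numeric vector: completed fraction per participant.
#' @export
compute_compliance <- function(panel) {
  completed_counts(panel) / (panel$schedule$n_days * panel$schedule$beeps_per_day)
}

# Completed-prompt counts per participant (all items non-missing).
completed_counts <- function(panel) {
  ids <- panel_participants(panel)
  if (length(ids) == 0L) return(stats::setNames(integer(0), character(0)))
  complete <- stats::complete.cases(
    panel$records[, panel$variable_names, drop = FALSE])
  counts <- tapply(complete, panel$records$participant_id, sum)
  out <- stats::setNames(as.integer(counts[ids]), ids)
  out[is.na(out)] <- 0L
  out
}

#' Filter participants by completed-prompt count
#'
#' Retains exactly the participants who completed at least `min_completed`
#' prompts (default 50 of the scheduled 84, i.e. the 60% adherence rule).
#' All records of retained participants are kept, including missing-valued
#' ones, so item-level imputation can still run afterwards.
#'
#' @param panel An [ema_panel()].
#' @param min_completed Minimum number of fully answered prompts (default 50).
#' @return The filtered [ema_panel()].
#' @export
filter_compliance <- function(panel, min_completed = 50) {
  stopifnot(is_count(min_completed),
            min_completed <= panel$schedule$n_days * panel$schedule$beeps_per_day)
  counts <- completed_counts(panel)
  keep <- names(counts)[counts >= min_completed]
  if (length(keep) == 0L)
    warning("no participant meets the compliance threshold")
  records <- panel$records[panel$records$participant_id %in% keep, ,
                           drop = FALSE]
  ema_panel(records, panel$schedule, panel$variable_names,
            standardized = panel$standardized)
}

#' Pooled z-scoring of panel items
#'
#' Centers and scales each item by its pooled mean and SD across all
#' non-missing observations of all participants, so fitted coefficients read
#' as standardized effects. Returns the scaling record needed for exact
#' inversion by [destandardize_panel()].
#'
#' @param panel An [ema_panel()] on the raw 0-100 scale.
#' @return List with elements `panel` (standardized) and `scaling`
#'   (data frame: variable, mean, sd).
#' @export
standardize_panel <- function(panel) {
  vals <- panel_values(panel)
  mu <- colMeans(vals, na.rm = TRUE)
  sd <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  zero <- which(!is.finite(sd) | sd == 0)
  if (length(zero))
    stop("zero-variance variable: ", panel$variable_names[zero[1L]])
  z <- sweep(sweep(vals, 2L, mu, "-"), 2L, sd, "/")
  list(panel = panel_set_values(panel, z, standardized = TRUE),
       scaling = data.frame(variable = panel$variable_names,
                            mean = unname(mu), sd = unname(sd)))
}

#' Invert pooled z-scoring
#'
#' @param panel A standardized [ema_panel()].
#' @param scaling The scaling record from [standardize_panel()].
#' @return The panel on the original scale.
#' @export
destandardize_panel <- function(panel, scaling) {
  stopifnot(identical(scaling$variable, panel$variable_names))
  z <- panel_values(panel)
  raw <- sweep(sweep(z, 2L, scaling$sd, "*"), 2L, scaling$mean, "+")
  panel_set_values(panel, raw, standardized = FALSE)
}

#' Build lagged design matrices
#'
#' Chains each participant's occasions in (day, beep) order with no gap at
#' day boundaries: each day's last beep is the lagged predictor of the next
#' day's first beep. The first `lag` occasions per participant contribute no
#' outcome row (they are conditioned on). Covariate columns are an intercept
#' plus, optionally, beep-of-day indicators (reference = first beep) or the
#' continuous clock time scaled to [0, 1], plus an optional linear day trend.
#'
#' @param panel A fully observed [ema_panel()] (run [impute_chained()] first).
#' @param lag Lag order `p` (>= 1).
#' @param covariates `"beep"` (categorical indicators, the default),
#'   `"clock"` (continuous time of day), or `"none"`.
#' @param trend Add a linear day-trend column scaled to [0, 1]?
#' @return An object of class `design_pair`: matrices `outcomes`
#'   (rows = usable occasions, cols = items) and `predictors`
#'   (intercept + covariates + `n_vars * lag` lagged values), plus
#'   `row_participant` aligning rows to participants.
#' @export
build_design <- function(panel, lag, covariates = c("beep", "clock", "none"),
                         trend = FALSE) {
  covariates <- match.arg(covariates)
  stopifnot(is_count(lag), lag >= 1)
  vals <- panel_values(panel)
  if (anyNA(vals))
    stop("panel contains missing values; impute before building designs")
  d <- ncol(vals)
  B <- panel$schedule$beeps_per_day
  D <- panel$schedule$n_days

  cov_of <- function(rec) {
    out <- matrix(1, nrow(rec), 1L, dimnames = list(NULL, "intercept"))
    if (covariates == "beep" && B > 1L) {
      ind <- outer(rec$beep, 2:B, "==") * 1
      colnames(ind) <- paste0("beep_", 2:B)
      out <- cbind(out, ind)
    } else if (covariates == "clock") {
      out <- cbind(out, clock = rec$clock_time / 1440)
    }
    if (trend)
      out <- cbind(out, day_trend = (rec$day - 1) / max(1L, D - 1L))
    out
  }

  ids <- panel_participants(panel)
  Ys <- Xs <- who <- vector("list", length(ids))
  dropped <- character(0)
  for (i in seq_along(ids)) {
    rows <- which(panel$records$participant_id == ids[i])
    Ti <- length(rows)
    if (Ti <= lag) { dropped <- c(dropped, ids[i]); next }
    v <- vals[rows, , drop = FALSE]
    keep <- (lag + 1L):Ti
    lagged <- do.call(cbind, lapply(seq_len(lag), function(l) {
      block <- v[keep - l, , drop = FALSE]
      colnames(block) <- paste0(panel$variable_names, "_lag", l)
      block
    }))
    Ys[[i]] <- v[keep, , drop = FALSE]
    Xs[[i]] <- cbind(cov_of(panel$records[rows[keep], , drop = FALSE]), lagged)
    who[[i]] <- rep(ids[i], length(keep))
  }
  if (length(dropped))
    warning("dropped participants with <= lag occasions: ",
            paste(dropped, collapse = ", "))
  outcomes <- do.call(rbind, Ys)
  predictors <- do.call(rbind, Xs)
  if (is.null(outcomes)) stop("no usable occasions at lag ", lag)
  colnames(outcomes) <- panel$variable_names
  n_cov_cols <- ncol(predictors) - d * lag
  structure(list(outcomes = outcomes, predictors = predictors,
                 row_participant = unlist(who), lag = as.integer(lag),
                 n_covariate_cols = n_cov_cols,
                 variable_names = panel$variable_names),
            class = "design_pair")
}

#' @export
print.design_pair <- function(x, ...) {
  cat(sprintf(
    "Design pair: %d outcome rows, %d predictor columns (lag %d, %d covariate cols), %d participants\n",
    nrow(x$outcomes), ncol(x$predictors), x$lag, x$n_covariate_cols,
    length(unique(x$row_participant))))
  invisible(x)
}
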