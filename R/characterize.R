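#' One-way ANOVA with generalised eta-squared
#'
#' Exact between/within decomposition: `SS_total = SS_num + SS_den`,
#' `F = (SS_num/df_num) / (SS_den/df_den)`, p from the F distribution, and
#' for this one-way design the generalised eta-squared is
#' `SS_num / (SS_num + SS_den)`.
#'
#' @param values Numeric outcome vector; `NA`s are dropped listwise together
#'   with their group entry.
#' @param groups Group labels (coerced to factor).
#' @return An object of class `anova_result` with fields `ss_num`, `ss_den`,
#'   `df_num`, `df_den`, `f`, `p`, `eta2_g`.
#' @export
oneway_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group with fewer than two observations: ",
         names(sizes)[which(sizes < 2L)[1L]])
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ss_num <- sum(sizes * (means - grand) ^ 2)
  ss_den <- sum((values - means[groups]) ^ 2)
  df_num <- nlevels(groups) - 1L
  df_den <- length(values) - nlevels(groups)
  # Identical group means (ss_num = 0) give F = 0 even when ss_den is also 0.
  f <- if (ss_num == 0) 0 else (ss_num / df_num) / (ss_den / df_den)
  eta2 <- if (ss_num == 0) 0 else ss_num / (ss_num + ss_den)
  structure(list(ss_num = ss_num, ss_den = ss_den,
                 df_num = df_num, df_den = df_den, f = f,
                 p = stats::pf(f, df_num, df_den, lower.tail = FALSE),
                 eta2_g = eta2,
                 group_means = means, group_sizes = as.integer(sizes)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.4g, eta2_g = %.3f\n",
              x$df_num, x$df_den, x$f, x$p, x$eta2_g))
  invisible(x)
}

#' ANOVA statistics from printed sums of squares
#'
#' Recovers `F`, `p` and generalised eta-squared from a reported
#' sums-of-squares decomposition, e.g. when checking a published one-way
#' ANOVA table.
#'
#' @param ss_num,ss_den Between- and within-group sums of squares.
#' @param df_num,df_den Corresponding degrees of freedom.
#' @return List with `f`, `p`, `eta2_g`.
#' @export
anova_from_ss <- function(ss_num, ss_den, df_num, df_den) {
  stopifnot(ss_num >= 0, ss_den >= 0, df_num >= 1, df_den >= 1)
  f <- (ss_num / df_num) / (ss_den / df_den)
  list(f = f, p = stats::pf(f, df_num, df_den, lower.tail = FALSE),
       eta2_g = ss_num / (ss_num + ss_den))
}

#' Tukey HSD pairwise contrasts
#'
#' All pairwise mean differences with studentized-range p-values and
#' simultaneous confidence intervals (Tukey-Kramer for unequal group
#' sizes), using the error degrees of freedom of the one-way ANOVA. The
#' difference for pair `(a, b)` follows the `delta_(b-a)` convention:
#' `mean(b) - mean(a)` with `a` the earlier factor level.
#'
#' @inheritParams oneway_anova
#' @param alpha Family-wise error rate for the intervals (default 0.05).
#' @return Data frame with one row per unordered pair: `contrast`
#'   (`"b-a"`), `delta`, `lwr`, `upr`, `p`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  an <- oneway_anova(values, groups)
  keep <- !is.na(values) & !is.na(groups)
  groups <- droplevels(as.factor(groups[keep]))
  lev <- levels(groups)
  k <- length(lev)
  mse <- an$ss_den / an$df_den
  sizes <- stats::setNames(an$group_sizes, lev)
  means <- an$group_means
  pairs <- utils::combn(lev, 2L)
  out <- data.frame(contrast = character(0), delta = numeric(0),
                    lwr = numeric(0), upr = numeric(0), p = numeric(0))
  qcrit <- stats::qtukey(1 - alpha, k, an$df_den)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    delta <- unname(means[b] - means[a])
    se <- sqrt(mse / 2 * (1 / sizes[a] + 1 / sizes[b]))
    p <- stats::ptukey(abs(delta) / se, k, an$df_den, lower.tail = FALSE)
    out[j, ] <- list(sprintf("%s-%s", b, a), delta,
                     delta - qcrit * se, delta + qcrit * se, unname(p))
  }
  out
}

# Log-probability of an r x c table under the fixed-margins multivariate
# hypergeometric distribution.
table_logprob <- function(tab, rs = rowSums(tab), cs = colSums(tab)) {
  sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# Enumerate all nonnegative integer tables with the given margins, calling
# fun(logprob) for each.
enumerate_tables <- function(rs, cs, fun) {
  r <- length(rs); cc <- length(cs)
  tab <- matrix(0L, r, cc)
  fill_row <- function(i, col_left) {
    if (i == r) {
      if (any(col_left < 0L)) return(invisible())
      tab[r, ] <<- col_left
      fun(table_logprob(tab, rs, cs))
      return(invisible())
    }
    fill_cell <- function(i, j, left_in_row, col_left) {
      if (j == cc) {
        if (left_in_row > col_left[cc]) return(invisible())
        tab[i, cc] <<- left_in_row
        fill_row(i + 1L, col_left - tab[i, ])
        return(invisible())
      }
      for (v in 0:min(left_in_row, col_left[j])) {
        tab[i, j] <<- v
        fill_cell(i, j + 1L, left_in_row - v, col_left)
      }
    }
    fill_cell(i, 1L, rs[i], col_left)
  }
  fill_row(1L, cs)
}

#' Exact Fisher test for an r x c table
#'
#' Enumerates every table sharing the observed margins, computes each one's
#' multivariate hypergeometric probability via log-factorial accumulation,
#' and returns the two-sided p-value under the probability-ordering rule:
#' the summed probability of all tables no more probable than the observed
#' one (with the customary 1e-7 relative tie tolerance).
#'
#' @param table Nonnegative integer count matrix with total at most 10,000.
#' @param details Also return the observed table's probability and the total
#'   enumerated mass (which must be 1)?
#' @return The two-sided p-value, or, with `details = TRUE`, a list
#'   `p`, `logp_obs`, `total_mass`, `n_tables`. A zero row or column margin
#'   is degenerate and yields `p = 1` with a warning.
#' @export
fisher_exact_rxc <- function(table, details = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("table must hold nonnegative integer counts")
  if (sum(tab) > 10000) stop("table total exceeds the enumeration bound")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate margin (zero row or column total); p = 1")
    return(if (details) list(p = 1, logp_obs = 0, total_mass = 1,
                             n_tables = 1L) else 1)
  }
  logp_obs <- table_logprob(tab, rs, cs)
  cutoff <- logp_obs + 1e-7
  acc <- new.env()
  acc$p <- 0; acc$mass <- 0; acc$n <- 0L
  enumerate_tables(rs, cs, function(lp) {
    pr <- exp(lp)
    acc$mass <- acc$mass + pr
    acc$n <- acc$n + 1L
    if (lp <= cutoff) acc$p <- acc$p + pr
  })
  p <- min(1, acc$p)
  if (details)
    list(p = p, logp_obs = logp_obs, total_mass = acc$mass, n_tables = acc$n)
  else p
}

#' Pearson chi-squared test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins and
#' `df = (r - 1)(c - 1)`. No continuity correction.
#'
#' @param table Nonnegative count matrix with no zero margins.
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chisq <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("table must hold nonnegative counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in table")
  E <- outer(rs, cs) / sum(tab)
  if (any(E == 0)) stop("zero expected cell")
  stat <- sum((tab - E) ^ 2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Between-cluster characterisation of a trait table
#'
#' Runs a one-way ANOVA (with generalised eta-squared) of every numeric
#' trait on cluster membership, with listwise deletion per trait, plus
#' Tukey HSD contrasts; categorical columns get a Pearson chi-squared test
#' and, when requested, the exact Fisher test.
#'
#' @param traits Data frame with a `cluster` column, numeric trait columns
#'   and optional factor columns.
#' @param outcomes Numeric trait columns to test (default: every numeric
#'   column except `cluster`).
#' @param categorical Factor/character columns to cross-tabulate against
#'   cluster (default: all such columns).
#' @param fisher_for Subset of `categorical` that should use the exact
#'   Fisher test (e.g. sparse tables such as gender); others use Pearson
#'   chi-squared.
#' @param p_adjust_method Optional multiplicity correction applied to the
#'   ANOVA p-values (a `stats::p.adjust` method); `"none"` (default)
#'   reports unadjusted values.
#' @return List with `anova` (one row per outcome: ss_num, ss_den, df, F,
#'   p, eta2_g), `tukey` (per-outcome contrast tables) and `categorical`
#'   (per-column test results with the underlying table).
#' @export
characterize_clusters <- function(traits, outcomes = NULL, categorical = NULL,
                                  fisher_for = "gender",
                                  p_adjust_method = "none") {
  stopifnot("cluster" %in% names(traits))
  cl <- factor(traits$cluster)
  if (is.null(outcomes))
    outcomes <- names(traits)[vapply(traits, is.numeric, logical(1))]
  outcomes <- setdiff(outcomes, "cluster")
  if (is.null(categorical))
    categorical <- names(traits)[vapply(traits, function(x)
      is.factor(x) || is.character(x), logical(1))]
  categorical <- setdiff(categorical, "participant_id")

  an_rows <- list(); tk <- list()
  for (v in outcomes) {
    a <- oneway_anova(traits[[v]], cl)
    an_rows[[v]] <- data.frame(outcome = v, ss_num = a$ss_num,
                               ss_den = a$ss_den, df_num = a$df_num,
                               df_den = a$df_den, f = a$f, p = a$p,
                               eta2_g = a$eta2_g)
    tk[[v]] <- tukey_hsd(traits[[v]], cl)
  }
  anova_tab <- do.call(rbind, an_rows)
  rownames(anova_tab) <- NULL
  anova_tab$p_adj <- stats::p.adjust(anova_tab$p, method = p_adjust_method)

  cat_res <- list()
  for (v in categorical) {
    keep <- !is.na(traits[[v]])
    tab <- table(cl[keep], traits[[v]][keep])
    cat_res[[v]] <- if (v %in% fisher_for)
      list(test = "fisher", table = tab, p = fisher_exact_rxc(tab))
    else c(list(test = "chisq", table = tab), pearson_chisq(tab))
  }
  list(anova = anova_tab, tukey = tk, categorical = cat_res)
}
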