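#' Coefficient heatmap matrix for one cluster
#'
#' Lays a cluster's lagged coefficients out the way they are displayed:
#' rows are predictor variables with craving and hunger first, and columns
#' are outcome variables grouped in one block per lag ("lag quadrants"),
#' each block ending with hunger then craving. Cell (predictor r, outcome c
#' at lag l) holds `A[[l]][c, r]`, on whatever scale the model was fitted
#' (standardized when the panel was z-scored).
#'
#' @param fit An `lcvar_fit` from [run_em()] or a grid's selected fit.
#' @param cluster Cluster index.
#' @return A labeled matrix with attributes `lag`, `row_vars`
#'   (predictor order) and `col_vars` (per-block outcome order).
#' @export
heatmap_matrix <- function(fit, cluster) {
  stopifnot(cluster >= 1, cluster <= length(fit$clusters))
  model <- fit$clusters[[cluster]]
  vn <- fit$variable_names %||% paste0("item_", seq_len(nrow(model$Sigma)))
  special <- c("craving", "hunger")
  row_vars <- if (all(special %in% vn))
    c(special, setdiff(vn, special)) else vn
  col_vars <- if (all(special %in% vn))
    c(setdiff(vn, special), "hunger", "craving") else vn
  p <- model$lag
  d <- length(vn)
  out <- matrix(NA_real_, d, d * p,
                dimnames = list(row_vars,
                                paste0(rep(col_vars, p), "_lag",
                                       rep(seq_len(p), each = d))))
  for (l in seq_len(p))
    out[, (l - 1L) * d + seq_len(d)] <-
      t(model$A[[l]][match(col_vars, vn), match(row_vars, vn), drop = FALSE])
  attr(out, "lag") <- p
  attr(out, "row_vars") <- row_vars
  attr(out, "col_vars") <- col_vars
  out
}

#' Reassemble lag matrices from a heatmap matrix
#'
#' Exact inverse of [heatmap_matrix()]: returns the list of `A` matrices in
#' the model's own variable order.
#'
#' @param hm A matrix produced by [heatmap_matrix()].
#' @param variable_names The model's variable order.
#' @return List of `p` coefficient matrices.
#' @export
heatmap_to_arrays <- function(hm, variable_names) {
  p <- attr(hm, "lag")
  d <- length(variable_names)
  row_vars <- attr(hm, "row_vars")
  col_vars <- attr(hm, "col_vars")
  lapply(seq_len(p), function(l) {
    block <- hm[, (l - 1L) * d + seq_len(d), drop = FALSE]
    A <- t(block)[match(variable_names, col_vars),
                  match(variable_names, row_vars), drop = FALSE]
    dimnames(A) <- NULL
    A
  })
}

#' Per-cluster daytime-course means
#'
#' Mean of every item at every scheduled beep, separately per cluster, on
#' the raw 0-100 scale and over non-missing observations only (use the
#' pre-imputation panel so the courses describe what was actually observed).
#'
#' @param panel An [ema_panel()] on the raw scale.
#' @param labels Named participant -> cluster vector covering the panel's
#'   participants (e.g. a fit's `hard_labels`).
#' @return An object of class `daytime_course`: arrays `values` and
#'   `counts`, both cluster x beep x variable; means are `NA` (flagged)
#'   where no observation contributes.
#' @export
daytime_means <- function(panel, labels) {
  ids <- panel_participants(panel)
  if (!all(ids %in% names(labels)))
    stop("labels must cover every participant in the panel")
  K <- max(labels)
  B <- panel$schedule$beeps_per_day
  d <- length(panel$variable_names)
  vals <- panel_values(panel)
  cl <- labels[panel$records$participant_id]
  bp <- panel$records$beep
  values <- array(NA_real_, c(K, B, d),
                  dimnames = list(paste0("cluster_", seq_len(K)),
                                  paste0("beep_", seq_len(B)),
                                  panel$variable_names))
  counts <- array(0L, dim(values), dimnames = dimnames(values))
  for (k in seq_len(K)) {
    for (b in seq_len(B)) {
      rows <- which(cl == k & bp == b)
      if (!length(rows)) next
      sub <- vals[rows, , drop = FALSE]
      counts[k, b, ] <- colSums(!is.na(sub))
      m <- colMeans(sub, na.rm = TRUE)
      m[counts[k, b, ] == 0L] <- NA_real_
      values[k, b, ] <- m
    }
  }
  structure(list(values = values, counts = counts), class = "daytime_course")
}

#' @export
print.daytime_course <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("Daytime course: %d cluster(s) x %d beeps x %d variables\n",
              dm[1L], dm[2L], dm[3L]))
  invisible(x)
}

#' Flatten a daytime course to a long data frame
#'
#' @param course A `daytime_course` from [daytime_means()].
#' @return Data frame with columns cluster, beep, variable, mean, n.
#' @export
daytime_course_table <- function(course) {
  dn <- dimnames(course$values)
  grid <- expand.grid(cluster = seq_along(dn[[1L]]),
                      beep = seq_along(dn[[2L]]),
                      variable = dn[[3L]], stringsAsFactors = FALSE)
  idx <- cbind(grid$cluster, grid$beep, match(grid$variable, dn[[3L]]))
  grid$mean <- course$values[idx]
  grid$n <- course$counts[idx]
  grid[order(grid$cluster, grid$variable, grid$beep), ]
}
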