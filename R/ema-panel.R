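#' EMA panel container
#'
#' Long-format multivariate time series of repeated smartphone prompts
#' ("beeps"). One record per (participant, day, beep); item values live on a
#' 0-100 slider scale, with `NA` marking an unanswered item. The schedule
#' (days, beeps per day, beep clock times) defines the compliance
#' denominator, so records may be missing-valued but are never silently
#' absent after construction through [simulate_panel()] or
#' [read_long_table()].
#'
#' @param records Data frame with columns `participant_id`, `day`, `beep`,
#'   `clock_time` (minutes since midnight), then one numeric column per item.
#' @param schedule List with `n_days`, `beeps_per_day`, `beep_times`
#'   (a vector of `beeps_per_day` clock times in minutes).
#' @param variable_names Item column names; defaults to every column after
#'   `clock_time`.
#' @param standardized Logical; when `TRUE` the 0-100 range check is waived
#'   (used for z-scored panels).
#'
#' @return An object of class `ema_panel`.
#' @export
ema_panel <- function(records, schedule, variable_names = NULL,
                      standardized = FALSE) {
  records <- as.data.frame(records)
  meta <- c("participant_id", "day", "beep", "clock_time")
  if (!all(meta %in% names(records)))
    stop("records must contain columns: ", paste(meta, collapse = ", "))
  if (is.null(variable_names))
    variable_names <- setdiff(names(records), meta)
  if (length(variable_names) < 1L) stop("panel needs at least one item column")
  stopifnot(is.list(schedule),
            is_count(schedule$n_days), is_count(schedule$beeps_per_day),
            length(schedule$beep_times) == schedule$beeps_per_day)
  records$participant_id <- as.character(records$participant_id)
  records$day <- as.integer(records$day)
  records$beep <- as.integer(records$beep)

  if (nrow(records) > 0L) {
    key <- paste(records$participant_id, records$day, records$beep)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("duplicate (participant, day, beep) record: ", dup)
    }
    if (any(records$day < 1L | records$day > schedule$n_days))
      stop("day outside schedule range 1..", schedule$n_days)
    if (any(records$beep < 1L | records$beep > schedule$beeps_per_day))
      stop("beep outside schedule range 1..", schedule$beeps_per_day)
    vals <- as.matrix(records[, variable_names, drop = FALSE])
    if (!standardized) {
      bad <- which(!is.na(vals) & (vals < 0 | vals > 100))
      if (length(bad)) {
        stop(sprintf("item value out of [0, 100]: %g (variable %s)",
                     vals[bad[1L]],
                     variable_names[(bad[1L] - 1L) %/% nrow(vals) + 1L]))
      }
    }
    ord <- order(records$participant_id, records$day, records$beep)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records, schedule = schedule,
                 variable_names = variable_names,
                 standardized = isTRUE(standardized)),
            class = "ema_panel")
}

#' The standard six-beep day schedule
#'
#' Prompts at 9:00, 11:30, 14:00, 16:30, 19:00 and 21:30, expressed in
#' minutes since midnight.
#'
#' @param n_days Number of study days (default 14).
#' @return A schedule list usable by [ema_panel()].
#' @export
default_schedule <- function(n_days = 14) {
  list(n_days = as.integer(n_days), beeps_per_day = 6L,
       beep_times = c(540, 690, 840, 990, 1140, 1290))
}

#' Names of the fourteen momentary items
#'
#' Five positive affect items, five negative affect items, two stress-coping
#' items, hunger and food craving, in the conventional order used throughout
#' the package.
#'
#' @return Character vector of length 14.
#' @export
ema_variable_names <- function() {
  c("cheerful", "enthusiastic", "relaxed", "calm", "active",
    "irritated", "worried", "depressed", "bored", "stressed",
    "coping_now", "coping_ahead", "hunger", "craving")
}

#' Item values of a panel as a numeric matrix
#'
#' Rows follow the panel's record order (participant, day, beep); columns
#' are the items. Missing observations are `NA`.
#'
#' @param panel An [ema_panel()].
#' @return Numeric matrix, records x variables.
#' @export
panel_values <- function(panel) {
  as.matrix(panel$records[, panel$variable_names, drop = FALSE])
}

# Replace item values, preserving metadata columns and validation status.
panel_set_values <- function(panel, values, standardized = panel$standardized) {
  stopifnot(nrow(values) == nrow(panel$records),
            ncol(values) == length(panel$variable_names))
  panel$records[, panel$variable_names] <- values
  ema_panel(panel$records, panel$schedule, panel$variable_names,
            standardized = standardized)
}

#' Participants present in a panel
#'
#' @param panel An [ema_panel()].
#' @return Character vector of unique participant ids, in panel order.
#' @export
panel_participants <- function(panel) {
  unique(panel$records$participant_id)
}

#' @export
print.ema_panel <- function(x, ...) {
  cat(sprintf(
    "EMA panel: %d participants, %d records, %d items (%d days x %d beeps)%s\n",
    length(panel_participants(x)), nrow(x$records), length(x$variable_names),
    x$schedule$n_days, x$schedule$beeps_per_day,
    if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Read an EMA panel from a delimited long-format file
#'
#' Expects a comma-separated header `participant_id,day,beep,clock_time`
#' followed by one column per item; empty cells are missing values (the
#' convention for prompts that expired unanswered). The schedule is taken
#' from `schedule` when supplied, otherwise inferred from the file (maximum
#' day, maximum beep, modal clock time per beep).
#'
#' @param path File path.
#' @param schedule Optional schedule list; required when the data section is
#'   empty.
#' @param standardized Passed through to [ema_panel()].
#' @return An [ema_panel()].
#' @export
read_long_table <- function(path, schedule = NULL, standardized = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  meta <- c("participant_id", "day", "beep", "clock_time")
  if (!all(meta %in% names(df)))
    stop("header must contain: ", paste(meta, collapse = ", "))
  if (nrow(df) == 0L) {
    if (is.null(schedule))
      stop("empty data section: a schedule must be supplied")
    return(ema_panel(df, schedule, setdiff(names(df), meta),
                     standardized = standardized))
  }
  if (is.null(schedule)) {
    bt <- vapply(sort(unique(df$beep)), function(b) {
      tt <- df$clock_time[df$beep == b]
      as.numeric(names(sort(table(tt), decreasing = TRUE))[1L])
    }, numeric(1))
    schedule <- list(n_days = max(df$day), beeps_per_day = max(df$beep),
                     beep_times = bt)
  }
  ema_panel(df, schedule, setdiff(names(df), meta),
            standardized = standardized)
}

#' Write an EMA panel to a delimited long-format file
#'
#' Inverse of [read_long_table()]: comma-separated, "." decimal, empty cell
#' for missing.
#'
#' @param panel An [ema_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(panel, path) {
  utils::write.csv(panel$records, path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}
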