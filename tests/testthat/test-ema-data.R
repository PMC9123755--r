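test_that("long-table round trip preserves records and validates input", {
  sp <- recovery_sim(2, n = 4, missing_rate = 0.15)
  f <- tempfile(fileext = ".csv")
  write_long_table(sp$panel, f)
  back <- read_long_table(f)
  expect_equal(back$records, sp$panel$records)
  expect_equal(back$schedule$beep_times, sp$panel$schedule$beep_times)

  # Empty data section with an explicit schedule is a valid empty panel.
  f2 <- tempfile(fileext = ".csv")
  writeLines("participant_id,day,beep,clock_time,item_1", f2)
  empty <- read_long_table(f2, schedule = default_schedule())
  expect_equal(nrow(empty$records), 0)

  # Out-of-range and duplicate records are rejected by name.
  rec <- data.frame(participant_id = "A", day = 1, beep = 1:6,
                    clock_time = 1:6, item_1 = 50)
  rec$item_1[3] <- 101
  expect_error(ema_panel(rec, default_schedule(1)), "101")
  rec$item_1[3] <- 50
  rec$beep[2] <- 1
  expect_error(ema_panel(rec, default_schedule(1)), "duplicate")
})

test_that("compliance counts completed prompts against the full schedule", {
  # 2 participants x 1 day x 6 beeps, all answered: 12 records, per-day
  # compliance 1 when the schedule is a single day.
  rec <- expand.grid(participant_id = c("A", "B"), day = 1, beep = 1:6)
  rec$clock_time <- rec$beep * 100
  rec$item_1 <- 50; rec$item_2 <- 50
  p1 <- ema_panel(rec, list(n_days = 1, beeps_per_day = 6,
                            beep_times = (1:6) * 100))
  expect_equal(nrow(p1$records), 12)
  expect_equal(unname(compute_compliance(p1)), c(1, 1))

  # A prompt with any missing item is not completed.
  panel <- roster_panel(n_total = 3, n_low = 2, low_completed = 50)
  counts <- compute_compliance(panel) * 84
  expect_equal(unname(round(counts)), c(50, 50, 84))
  expect_equal(unname(compute_compliance(panel))[1], 50 / 84)

  low <- roster_panel(n_total = 1, n_low = 1, low_completed = 42)
  expect_equal(unname(compute_compliance(low)), 0.5)
})

test_that("compliance filter retains the >= 50 completions roster and is idempotent", {
  panel <- roster_panel(136, n_low = 21, low_completed = 49)
  kept <- filter_compliance(panel, 50)
  expect_equal(length(panel_participants(kept)), 115)
  # Boundary: exactly 50 completions is retained.
  boundary <- roster_panel(3, n_low = 2, low_completed = 50)
  expect_equal(length(panel_participants(filter_compliance(boundary, 50))), 3)
  # Idempotence and the no-op case.
  expect_identical(filter_compliance(kept, 50)$records, kept$records)
  full <- roster_panel(5, n_low = 0)
  expect_identical(filter_compliance(full, 50)$records, full$records)
  expect_warning(filter_compliance(roster_panel(2, 2, 10), 50),
                 "no participant")
})

test_that("pooled standardization is exact, invertible and order-preserving", {
  sp <- recovery_sim(3, n = 6, missing_rate = 0.1)
  st <- standardize_panel(sp$panel)
  z <- panel_values(st$panel)
  expect_lt(max(abs(colMeans(z, na.rm = TRUE))), 1e-12)
  expect_equal(unname(apply(z, 2, sd, na.rm = TRUE)), rep(1, 4))
  # Direct formula: a variable with mean 50 and SD 10 maps 60 to 1.0.
  v1 <- panel_values(sp$panel)[, 1]
  expect_equal(z[, 1], (v1 - mean(v1, na.rm = TRUE)) / sd(v1, na.rm = TRUE))
  expect_equal((60 - 50) / 10, 1.0)
  # Idempotence up to the (already unit) scaling record.
  st2 <- standardize_panel(st$panel)
  expect_lt(max(abs(panel_values(st2$panel) - z), na.rm = TRUE), 1e-12)
  # Round trip.
  back <- destandardize_panel(st$panel, st$scaling)
  expect_lt(max(abs(panel_values(back) - panel_values(sp$panel)),
                na.rm = TRUE), 1e-10)
  # Ordering within a variable is preserved.
  expect_identical(order(v1[!is.na(v1)]), order(z[!is.na(z[, 1]), 1]))
  # Zero-variance variables are refused by name.
  const <- roster_panel(2, 0)
  expect_error(standardize_panel(const), "item_1")
})

test_that("design construction chains days and applies the day-boundary rule", {
  # One participant, 2 days x 6 beeps, lag 1: 11 outcome rows, and the row
  # for day 2 beep 1 uses day 1 beep 6 as its lagged predictor.
  set.seed(11)
  rec <- expand.grid(beep = 1:6, day = 1:2)
  rec <- data.frame(participant_id = "A", day = rec$day, beep = rec$beep,
                    clock_time = rec$beep * 100,
                    y = round(runif(12, 10, 90), 1))
  panel <- ema_panel(rec, list(n_days = 2, beeps_per_day = 6,
                               beep_times = (1:6) * 100))
  dp <- build_design(panel, 1)
  expect_equal(nrow(dp$outcomes), 11)
  cross_day_row <- which(dp$predictors[, "beep_2"] == 0 &
                           rowSums(dp$predictors[, paste0("beep_", 2:6)]) == 0)
  day2_beep1 <- panel$records$day == 2 & panel$records$beep == 1
  day1_beep6 <- panel$records$day == 1 & panel$records$beep == 6
  expect_equal(unname(dp$predictors[cross_day_row, "y_lag1"]),
               panel$records$y[day1_beep6])
  expect_equal(unname(dp$outcomes[cross_day_row, "y"]),
               panel$records$y[day2_beep1])

  # T - p rows at lag 3 on a full 84-occasion series.
  sp1 <- recovery_sim(4, n = 1)
  expect_equal(nrow(build_design(sp1$panel, 3)$outcomes), 81)

  # Participants with <= p occasions are dropped with a warning.
  tiny <- series_panel(c(10, 20))
  expect_warning(expect_error(build_design(tiny, 2), "no usable occasions"),
                 "dropped")
})

test_that("design rank and row counts match the closed forms", {
  sp <- recovery_sim(5, n = 8)
  for (p in c(1, 2)) {
    dp <- build_design(sp$panel, p)
    expect_equal(nrow(dp$outcomes), 8 * (84 - p))
    expect_equal(ncol(dp$predictors), 1 + 5 + 4 * p)
    expect_equal(qr(dp$predictors)$rank, 1 + 5 + 4 * p)
  }
  expect_error(build_design(recovery_sim(5, n = 2, missing_rate = 0.2)$panel, 1),
               "missing")
})
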