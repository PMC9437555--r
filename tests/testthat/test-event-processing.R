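test_that("event-log parsing maps fields, sorts, and keeps duplicates", {
  ev <- parse_event_log(ev_row("P001", "2014-03-02T08:15:00", "intake"))
  expect_equal(ev$participant_id, "P001")
  expect_equal(ev$timestamp, as.POSIXct("2014-03-02 08:15:00", tz = "UTC"))
  expect_equal(as.character(ev$signal), "intake")

  # header-only file -> empty sequence
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,timestamp,signal", path)
  expect_equal(nrow(read_event_log(path)), 0)

  # duplicates in the same minute are retained (dedup happens downstream)
  two <- parse_event_log(rbind(
    ev_row("P001", "2014-03-02T08:15:00", "intake"),
    ev_row("P001", "2014-03-02T08:15:30", "intake")
  ))
  expect_equal(nrow(two), 2)

  # events come back sorted by participant then time
  shuffled <- parse_event_log(rbind(
    ev_row("P2", "2014-03-05T08:00:00", "heartbeat"),
    ev_row("P1", "2014-03-06T08:00:00", "intake"),
    ev_row("P1", "2014-03-04T08:00:00", "intake")
  ))
  expect_equal(shuffled$participant_id, c("P1", "P1", "P2"))
  expect_true(!is.unsorted(shuffled$timestamp[shuffled$participant_id == "P1"]))
})

test_that("malformed timestamps and unknown signals are rejected by row", {
  expect_error(
    parse_event_log(rbind(
      ev_row("P1", "2014-03-02T08:00:00", "intake"),
      ev_row("P1", "not-a-time", "intake")
    )),
    "malformed timestamp.*2"
  )
  expect_error(
    parse_event_log(ev_row("P1", "2014-03-02T08:00:00", "opened")),
    "unknown signal.*opened"
  )
})

test_that("daily status follows the signal-dominance rules for every signal subset", {
  # brute-force oracle over all non-empty subsets of {intake, heartbeat, none},
  # plus the empty day: intake dominates, then heartbeat, else missing
  subsets <- list(
    character(0), "intake", "heartbeat", "none",
    c("intake", "heartbeat"), c("intake", "none"), c("heartbeat", "none"),
    c("intake", "heartbeat", "none"),
    c("intake", "intake", "intake") # repeat openings count once
  )
  oracle <- function(sigs) {
    if ("intake" %in% sigs) "taken" else if ("heartbeat" %in% sigs) "missed" else "missing"
  }
  for (sigs in subsets) {
    ev <- if (length(sigs) == 0) {
      parse_event_log(data.frame(participant_id = character(0),
                                 timestamp = character(0),
                                 signal = character(0)))
    } else {
      events_from_days(list(sigs))
    }
    daily <- derive_daily_status(ev, as.Date("2014-03-01"), span_days = 1)
    expect_equal(as.character(daily$status), oracle(sigs),
                 label = paste("signals:", paste(sigs, collapse = "+")))
  }
})

test_that("daily derivation spans the full window and validates the issue date", {
  ev <- events_from_days(list("intake", "heartbeat"))
  daily <- derive_daily_status(ev, as.Date("2014-03-01"), span_days = 5)
  expect_equal(nrow(daily), 5)
  expect_equal(as.character(daily$status), c("taken", "missed", rep("missing", 3)))
  expect_error(derive_daily_status(ev, as.Date("2014-03-02"), span_days = 5),
               "precede")
  expect_error(
    derive_daily_status(
      parse_event_log(rbind(ev_row("P1", "2014-03-02T08:00:00", "intake"),
                            ev_row("P2", "2014-03-02T08:00:00", "intake"))),
      as.Date("2014-03-01"), 5),
    "single participant"
  )
})

test_that("first-week exclusion drops and re-indexes, and is idempotent", {
  daily <- random_daily(37)
  out <- apply_first_week_exclusion(daily)
  expect_equal(nrow(out), 30)
  expect_equal(out$day_index, 1:30)
  expect_equal(as.character(out$status), as.character(daily$status[8:37]))

  expect_equal(nrow(apply_first_week_exclusion(random_daily(7))), 0)

  d8 <- random_daily(8)
  d8$status[8] <- "taken"
  out8 <- apply_first_week_exclusion(d8)
  expect_equal(nrow(out8), 1)
  expect_equal(as.character(out8$status), "taken")

  # applying twice equals applying once
  expect_identical(apply_first_week_exclusion(out), out)
})

test_that("monthly aggregation applies the >4-missed-days rule and its boundaries", {
  mk <- function(statuses) tibble::tibble(
    participant_id = "P1", day_index = seq_along(statuses),
    status = factor(statuses, levels = c("taken", "missed", "missing")))

  # 4 missed of 30 observed -> good; 5 missed -> poor (boundary of the rule)
  expect_equal(as.character(
    aggregate_monthly(mk(rep(c("missed", "taken"), c(4, 26))))$category), "good")
  expect_equal(as.character(
    aggregate_monthly(mk(rep(c("missed", "taken"), c(5, 25))))$category), "poor")

  # fully unobserved window
  expect_equal(as.character(
    aggregate_monthly(mk(rep("missing", 30)))$category), "unobserved")

  # partially observed but evidently poor: observed 20 >= 15, missed 5 > 4
  m <- aggregate_monthly(mk(rep(c("missing", "missed", "taken"), c(10, 5, 15))))
  expect_equal(m$days_observed, 20)
  expect_equal(as.character(m$category), "poor")

  # under-observed and not evidently poor
  expect_equal(as.character(
    aggregate_monthly(mk(rep(c("missing", "taken"), c(20, 10))))$category),
    "unobserved")
})

test_that("monthly windows conserve days and match a brute-force recount", {
  set.seed(101)
  for (rep in 1:20) {
    n_days <- sample(10:60, 1)
    daily <- random_daily(n_days)
    monthly <- aggregate_monthly(daily, window_days = 30)

    # conservation: observed + missing = window_days in every window
    for (m in monthly$month_index) {
      in_window <- daily[daily$day_index > (m - 1) * 30 & daily$day_index <= m * 30, ]
      n_missing_recorded <- sum(in_window$status == "missing")
      n_absent <- 30 - nrow(in_window)
      row <- monthly[monthly$month_index == m, ]
      expect_equal(row$days_observed + n_missing_recorded + n_absent, 30)
      # brute-force recount of missed days
      expect_equal(row$days_missed, sum(in_window$status == "missed"))
    }
  }
})

test_that("repeating intake signals on a day never changes the monthly summary", {
  set.seed(7)
  days <- replicate(40, sample(c("intake", "heartbeat", "none"),
                               sample(1:2, 1), replace = TRUE),
                    simplify = FALSE)
  base <- events_from_days(days)
  # triple every intake signal
  tripled <- parse_event_log(
    base[rep(seq_len(nrow(base)), ifelse(base$signal == "intake", 3, 1)), ])
  pipeline <- function(ev) {
    derive_daily_status(ev, as.Date("2014-03-01"), 40) |>
      apply_first_week_exclusion() |>
      aggregate_monthly()
  }
  expect_equal(pipeline(base), pipeline(tripled), ignore_attr = TRUE)
})

test_that("full event pipeline matches a day-by-day recount on random streams", {
  set.seed(42)
  for (rep in 1:10) {
    n_days <- sample(20:60, 1)
    days <- replicate(n_days, {
      if (runif(1) < 0.2) character(0)
      else sample(c("intake", "heartbeat", "none"), sample(1:3, 1), replace = TRUE)
    }, simplify = FALSE)
    has_rows <- any(lengths(days) > 0)
    if (!has_rows) next
    ev <- events_from_days(days)
    monthly <- derive_daily_status(ev, as.Date("2014-03-01"), n_days) |>
      apply_first_week_exclusion() |>
      aggregate_monthly()

    # independent day-by-day oracle
    status_oracle <- vapply(days, function(s) {
      if ("intake" %in% s) "taken" else if ("heartbeat" %in% s) "missed" else "missing"
    }, character(1))
    post <- status_oracle[-(1:7)]
    if (length(post) == 0) {
      expect_equal(nrow(monthly), 0)
      next
    }
    windows <- split(post, (seq_along(post) - 1) %/% 30 + 1)
    expect_equal(monthly$days_missed,
                 unname(vapply(windows, function(w) sum(w == "missed"), numeric(1))))
    expect_equal(monthly$days_observed,
                 unname(vapply(windows, function(w) sum(w != "missing"), numeric(1))))
  }
})
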