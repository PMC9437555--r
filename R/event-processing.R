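#' Parse a pill-box device event log
#'
#' Validates and normalizes raw telemetry from an electronic adherence
#' monitoring device. Each row is one transmitted signal: `"intake"` (the
#' container was opened — a proxy for a dose taken), `"heartbeat"` (the device
#' was alive but not opened) or `"none"` (the device was malfunctioning).
#' Repeated signals on the same day are retained here; de-duplication to a
#' daily binary happens in [derive_daily_status()].
#'
#' @param x a data frame with columns `participant_id`, `timestamp`
#'   (ISO-8601 date-time) and `signal`.
#' @return a tibble of events sorted by participant and time, with `timestamp`
#'   parsed to POSIXct (UTC) and `signal` a factor with levels
#'   `intake`, `heartbeat`, `none`.
#' @seealso [read_event_log()] to read the delimited file from disk.
#' @export
parse_event_log <- function(x) {
  required <- c("participant_id", "timestamp", "signal")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_adh("event log is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ts <- lubridate::ymd_hms(as.character(x$timestamp), quiet = TRUE, tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort_adh(
      "malformed timestamp in event-log row(s): ",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""
    )
  }
  sig <- as.character(x$signal)
  unknown <- setdiff(unique(sig), c("intake", "heartbeat", "none"))
  if (length(unknown) > 0) {
    abort_adh("unknown signal label(s): ", paste(unknown, collapse = ", "))
  }
  tibble::tibble(
    participant_id = as.character(x$participant_id),
    timestamp = ts,
    signal = factor(sig, levels = c("intake", "heartbeat", "none"))
  ) |>
    dplyr::arrange(.data$participant_id, .data$timestamp)
}

#' Read a device event log from a CSV file
#'
#' @param path path to a CSV file with header
#'   `participant_id,timestamp,signal`.
#' @return see [parse_event_log()].
#' @export
read_event_log <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      timestamp = readr::col_character(),
      signal = readr::col_character()
    )
  )
  parse_event_log(raw)
}

#' Derive daily dose-taken status for one participant
#'
#' Collapses a participant's event stream to one record per day of device
#' possession. A day counts as `taken` if it has at least one `intake` signal
#' (only the first opening matters; subsequent openings on the same day are
#' ignored), `missed` if it has a `heartbeat` and no intake, and `missing` if
#' it has only a `none` (malfunction) signal or no signal at all — absence of
#' a heartbeat also indicates non-functioning transmission, so silent days are
#' treated as missing rather than missed.
#'
#' @param events events for a single participant, as from [parse_event_log()].
#' @param issue_date the date the device was issued (day 1).
#' @param span_days number of days of observation to cover; exactly this many
#'   records are returned.
#' @return a tibble with `participant_id`, `day_index` (1-based) and `status`
#'   (factor: `taken`, `missed`, `missing`).
#' @examples
#' ev <- parse_event_log(data.frame(
#'   participant_id = "P1",
#'   timestamp = c("2014-03-01T08:00:00", "2014-03-01T20:00:00", "2014-03-02T08:00:00"),
#'   signal = c("intake", "intake", "heartbeat")
#' ))
#' derive_daily_status(ev, issue_date = "2014-03-01", span_days = 3)
#' @export
derive_daily_status <- function(events, issue_date, span_days) {
  stopifnot(span_days >= 1)
  issue_date <- as.Date(issue_date)
  pid <- unique(as.character(events$participant_id))
  if (length(pid) > 1) {
    abort_adh("derive_daily_status() expects events from a single participant, got ", length(pid))
  }
  if (length(pid) == 0) pid <- NA_character_

  if (nrow(events) > 0) {
    day <- as.integer(as.Date(events$timestamp, tz = "UTC") - issue_date) + 1L
    if (any(day < 1)) abort_adh("event(s) precede the device issue date")
    keep <- day <= span_days
    day <- day[keep]
    sig <- events$signal[keep]
  } else {
    day <- integer(0)
    sig <- factor(character(0), levels = c("intake", "heartbeat", "none"))
  }

  has_intake <- tabulate(day[sig == "intake"], nbins = span_days) > 0
  has_heartbeat <- tabulate(day[sig == "heartbeat"], nbins = span_days) > 0
  status <- ifelse(has_intake, "taken", ifelse(has_heartbeat, "missed", "missing"))
  tibble::tibble(
    participant_id = pid,
    day_index = seq_len(span_days),
    status = factor(status, levels = c("taken", "missed", "missing"))
  )
}

#' Drop the device run-in week
#'
#' Device novelty inflates openings during the first days of use, so the first
#' seven days after device issue are excluded and the remaining days are
#' re-indexed from 1 (month 1 therefore spans days 8–37 of device possession).
#' The returned tibble is tagged so a second application is a no-op.
#'
#' @param daily a daily-status tibble as from [derive_daily_status()] (may
#'   cover several participants).
#' @param run_in_days number of leading days to drop, default 7.
#' @return the daily tibble without the run-in days, `day_index` re-based to 1.
#' @export
apply_first_week_exclusion <- function(daily, run_in_days = 7) {
  if (isTRUE(attr(daily, "first_week_excluded"))) {
    return(daily)
  }
  out <- daily |>
    dplyr::filter(.data$day_index > run_in_days) |>
    dplyr::mutate(day_index = .data$day_index - as.integer(run_in_days))
  attr(out, "first_week_excluded") <- TRUE
  out
}

#' Aggregate daily adherence to dichotomized monthly adherence
#'
#' Days are grouped into consecutive non-overlapping windows of `window_days`
#' ("months"). Within each window, `days_missed` counts `missed` days and
#' `days_observed` counts non-`missing` days; days absent from the input also
#' count as missing, so `days_observed + missing days = window_days` always.
#' A window is `poor` if more than `missed_threshold` observed days were
#' missed (the national-guideline >4 days/month rule), `unobserved` if it has
#' fewer than `min_observed_days` classifiable days and is not already poor,
#' and `good` otherwise.
#'
#' @param daily post-exclusion daily tibble (one or more participants).
#' @param window_days window length in days, default 30.
#' @param missed_threshold maximum missed days compatible with good adherence,
#'   default 4 (so 5+ missed days is poor).
#' @param min_observed_days minimum classifiable days for a window to be
#'   categorized at all, default 15 (half the window).
#' @return tibble with `participant_id`, `month_index`, `days_observed`,
#'   `days_missed`, `category` (factor: `good`, `poor`, `unobserved`).
#' @export
aggregate_monthly <- function(daily, window_days = 30, missed_threshold = 4,
                              min_observed_days = 15) {
  stopifnot(window_days >= 1, missed_threshold >= 0, min_observed_days >= 0)
  daily |>
    dplyr::mutate(month_index = (.data$day_index - 1L) %/% as.integer(window_days) + 1L) |>
    dplyr::group_by(.data$participant_id, .data$month_index) |>
    dplyr::summarise(
      days_observed = sum(.data$status != "missing"),
      days_missed = sum(.data$status == "missed"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      category = factor(
        dplyr::case_when(
          .data$days_missed > missed_threshold ~ "poor",
          .data$days_observed < min_observed_days ~ "unobserved",
          TRUE ~ "good"
        ),
        levels = c("good", "poor", "unobserved")
      )
    )
}

#' Full electronic-monitoring derivation for a roster of participants
#'
#' Convenience wrapper: for every participant in `roster`, derives daily
#' status from the event log (participants with no events get all-missing
#' days), drops the run-in week, and aggregates to monthly categories.
#'
#' @param events parsed event log covering any number of participants.
#' @param roster tibble with `participant_id` and `issue_date`.
#' @param months number of 30-day months to derive, default 12.
#' @inheritParams aggregate_monthly
#' @param run_in_days run-in days excluded before month 1, default 7.
#' @return monthly adherence tibble, one row per participant-month.
#' @export
em_monthly <- function(events, roster, months = 12, window_days = 30,
                       missed_threshold = 4, min_observed_days = 15,
                       run_in_days = 7) {
  span <- run_in_days + months * window_days
  ev_split <- split(events, events$participant_id)
  purrr::map2(
    roster$participant_id, as.Date(roster$issue_date),
    function(pid, issued) {
      ev <- ev_split[[pid]] %||% events[0, ]
      derive_daily_status(ev, issued, span) |>
        dplyr::mutate(participant_id = pid) |>
        apply_first_week_exclusion(run_in_days) |>
        aggregate_monthly(window_days, missed_threshold, min_observed_days)
    }
  ) |>
    purrr::list_rbind()
}
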