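# Shared fixture builders: everything is generated in code at test time.

# one event-log row
ev_row <- function(pid, ts, signal) {
  data.frame(participant_id = pid, timestamp = ts, signal = signal,
             stringsAsFactors = FALSE)
}

# event log for one participant from a list day -> character vector of signals
events_from_days <- function(signals_by_day, pid = "P1",
                             issue_date = as.Date("2014-03-01")) {
  rows <- list()
  for (d in seq_along(signals_by_day)) {
    sigs <- signals_by_day[[d]]
    for (k in seq_along(sigs)) {
      rows[[length(rows) + 1]] <- ev_row(
        pid,
        sprintf("%sT%02d:%02d:00", issue_date + d - 1, 7 + k, 15),
        sigs[k]
      )
    }
  }
  parse_event_log(do.call(rbind, rows))
}

# random daily-status tibble for property tests
random_daily <- function(n_days, pid = "P1") {
  tibble::tibble(
    participant_id = pid,
    day_index = seq_len(n_days),
    status = factor(sample(c("taken", "missed", "missing"), n_days,
                           replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                    levels = c("taken", "missed", "missing"))
  )
}

# random non-degenerate 2x2 table with total n <= max_n
random_table <- function(max_n = 50) {
  repeat {
    cells <- stats::rmultinom(1, sample(4:max_n, 1), prob = runif(4, 0.05, 1))
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    if ((t$n11 + t$n01) > 0 && (t$n10 + t$n00) > 0) return(t)
  }
}

# expand a 2x2 table back into paired category vectors
table_to_pairs <- function(t) {
  list(
    a = factor(rep(c("poor", "poor", "good", "good"),
                   c(t$n11, t$n10, t$n01, t$n00)), levels = c("good", "poor")),
    b = factor(rep(c("poor", "good", "poor", "good"),
                   c(t$n11, t$n10, t$n01, t$n00)), levels = c("good", "poor"))
  )
}

# tweak a simulated cohort's config in place (for measurement-layer overrides)
within_cfg <- function(cohort, ...) {
  cohort$config <- utils::modifyList(cohort$config, list(...))
  cohort
}

# tweak a sim_config in place
within_trial_cfg <- function(cfg, ...) {
  utils::modifyList(cfg, list(...))
}

# small trend dataset simulated at given parameters (no event layer)
small_trend_data <- function(seed, n_clinics = 12, ppc = 8, months = 6,
                             beta0 = 2, beta_month = NULL, beta_arm = 0,
                             beta_interaction = NULL,
                             s2_clinic = 0.1, s2_participant = 2) {
  cfg <- sim_config(
    n_clinics = n_clinics, n_control_clinics = ceiling(n_clinics / 2),
    participants_per_clinic = ppc, months = months,
    beta0 = beta0,
    beta_month = beta_month %||% seq(-0.3, -1.5, length.out = months - 1),
    beta_arm = beta_arm,
    beta_interaction = beta_interaction %||% rep(0, months - 1),
    sigma2_clinic = s2_clinic, sigma2_participant = s2_participant
  )
  cohort <- simulate_cohort(cfg, seed = seed)
  dplyr::transmute(cohort$truth, clinic_id, participant_id, month_index,
                   arm, good)
}
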