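#' Configuration for the synthetic adherence trial
#'
#' Defaults reproduce the design and published random-effects structure of a
#' 39-clinic, twelve-month cluster-randomized adolescent ART cohort: 19
#' control / 20 intervention clinics, ~18 participants per clinic (~700
#' total), a declining categorical month trend on the log-odds scale, a small
#' clinic variance and a large participant variance. Measurement-layer
#' parameters are calibrated so the derived measures reproduce the field's
#' characteristic patterns: strong self-report over-reporting of adherence
#' and weak adherence-to-viral-load coupling (low sensitivity, high
#' specificity).
#'
#' @param n_clinics number of clinics (default 39).
#' @param n_control_clinics clinics assigned to the control arm (default 19;
#'   the remainder are intervention). Assignment is fixed, not re-randomized
#'   per seed.
#' @param participants_per_clinic participants recruited per clinic
#'   (default 18, totalling 702).
#' @param months follow-up months (default 12).
#' @param beta0 intercept log-odds of monthly good adherence (default 6.044).
#' @param beta_month length-`months - 1` vector of month effects vs month 1
#'   (defaults: the published declining trend).
#' @param beta_arm intervention main effect (default 0.339).
#' @param beta_interaction length-`months - 1` vector of month-by-arm
#'   interactions (defaults: published values; set to zeros for a
#'   no-interaction cohort).
#' @param sigma2_clinic clinic random-intercept variance (default 0.089).
#' @param sigma2_participant participant random-intercept variance
#'   (default 10.610).
#' @param missed_geom_prob geometric parameter for missed days given a poor
#'   month: days missed = 5 + truncated-geometric(p) on 0..25, mean ~9
#'   (default 0.2). Right-skewed, as real missed-day counts are.
#' @param sr_recall_prob probability a truly missed day is recalled in
#'   self-report (binomial thinning; default 0.332, calibrated so ~97% of
#'   month-12 control self-reports are good while electronic monitoring is
#'   notably lower).
#' @param malfunction_rate per-day probability the device emits only a
#'   malfunction ("none") signal (default 0.02).
#' @param vl_alpha0 log-odds of viral non-suppression for a good-adherent
#'   month 12 (default -0.745, i.e. ~32%).
#' @param vl_alpha1 added log-odds of non-suppression for a poor month 12
#'   (default 0.191 — deliberately weak coupling).
#' @param vl_cutoff suppression cutoff in copies/ml (default 50).
#' @param issue_date device issue date shared by all participants
#'   (default "2014-03-01").
#' @param run_in_days device run-in days preceding month 1 (default 7).
#' @param window_days days per adherence month (default 30).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_clinics = 39,
                       n_control_clinics = 19,
                       participants_per_clinic = 18,
                       months = 12,
                       beta0 = 6.044,
                       beta_month = c(-1.202, -1.787, -1.875, -2.177, -2.217,
                                      -2.166, -2.473, -2.373, -2.517, -1.798,
                                      -2.416),
                       beta_arm = 0.339,
                       beta_interaction = c(-0.415, -0.217, -0.091, -0.369,
                                            -0.069, 0.573, 0.021, 0.190,
                                            -0.176, -0.343, -0.116),
                       sigma2_clinic = 0.089,
                       sigma2_participant = 10.610,
                       missed_geom_prob = 0.2,
                       sr_recall_prob = 0.332,
                       malfunction_rate = 0.02,
                       vl_alpha0 = -0.745,
                       vl_alpha1 = 0.191,
                       vl_cutoff = 50,
                       issue_date = "2014-03-01",
                       run_in_days = 7,
                       window_days = 30) {
  cfg <- list(
    n_clinics = n_clinics, n_control_clinics = n_control_clinics,
    participants_per_clinic = participants_per_clinic, months = months,
    beta0 = beta0, beta_month = beta_month, beta_arm = beta_arm,
    beta_interaction = beta_interaction,
    sigma2_clinic = sigma2_clinic, sigma2_participant = sigma2_participant,
    missed_geom_prob = missed_geom_prob, sr_recall_prob = sr_recall_prob,
    malfunction_rate = malfunction_rate,
    vl_alpha0 = vl_alpha0, vl_alpha1 = vl_alpha1, vl_cutoff = vl_cutoff,
    issue_date = as.Date(issue_date), run_in_days = run_in_days,
    window_days = window_days
  )
  if (length(cfg$beta_month) != months - 1) {
    abort_adh("beta_month must have length months - 1 (", months - 1, ")")
  }
  if (length(cfg$beta_interaction) != months - 1) {
    abort_adh("beta_interaction must have length months - 1 (", months - 1, ")")
  }
  stopifnot(
    cfg$sigma2_clinic >= 0, cfg$sigma2_participant >= 0,
    cfg$sr_recall_prob >= 0, cfg$sr_recall_prob <= 1,
    cfg$malfunction_rate >= 0, cfg$malfunction_rate <= 1,
    cfg$missed_geom_prob > 0, cfg$missed_geom_prob < 1,
    cfg$n_control_clinics >= 1, cfg$n_control_clinics < cfg$n_clinics,
    cfg$months >= 1
  )
  structure(cfg, class = "sim_config")
}

# internal: truncated geometric on 0..max by inverse-cdf
rtrunc_geom <- function(n, p, max) {
  qgeom(runif(n) * pgeom(max, p), p)
}

#' Simulate the latent cohort: clinics, participants and monthly truth
#'
#' Draws clinic intercepts u ~ N(0, sigma2_clinic) and participant intercepts
#' v ~ N(0, sigma2_participant); each participant-month's good-adherence
#' probability is `logistic(beta0 + beta_month[m] + arm * (beta_arm +
#' beta_interaction[m]) + u + v)` and the indicator is drawn Bernoulli. True
#' missed days are uniform 0..4 in good months and 5 + truncated-geometric
#' (mean ~9) in poor months, so the category is always consistent with the
#' >4-days rule.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed; omit to continue the current RNG stream
#'   (as [simulate_trial()] does).
#' @return an object of class `cohort_truth`: list with `clinics`
#'   (clinic_id, arm, u), `participants` (participant_id, clinic_id, arm,
#'   age, age_group, sex, v), `truth` (participant-month eta, p_good, good,
#'   days_missed) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clinics <- tibble::tibble(
    clinic_id = sprintf("C%02d", seq_len(cfg$n_clinics)),
    arm = rep(c("control", "intervention"),
              c(cfg$n_control_clinics, cfg$n_clinics - cfg$n_control_clinics)),
    u = rnorm(cfg$n_clinics, 0, sqrt(cfg$sigma2_clinic))
  )
  n_part <- cfg$n_clinics * cfg$participants_per_clinic
  participants <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n_part)),
    clinic_id = rep(clinics$clinic_id, each = cfg$participants_per_clinic),
    age = sample(10:16, n_part, replace = TRUE,
                 prob = c(0.18, 0.17, 0.16, 0.15, 0.13, 0.11, 0.10)),
    sex = sample(c("female", "male"), n_part, replace = TRUE,
                 prob = c(0.56, 0.44))
  ) |>
    dplyr::left_join(clinics, by = "clinic_id") |>
    dplyr::mutate(
      age_group = ifelse(.data$age < 14, "10-13", "14-16"),
      v = rnorm(n_part, 0, sqrt(cfg$sigma2_participant))
    )

  bm <- c(0, cfg$beta_month)
  bi <- c(0, cfg$beta_interaction)
  truth <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    month_index = seq_len(cfg$months)
  ) |>
    dplyr::left_join(
      dplyr::select(participants, "participant_id", "clinic_id", "arm", "u", "v"),
      by = "participant_id"
    ) |>
    dplyr::mutate(
      is_intervention = as.numeric(.data$arm == "intervention"),
      eta = cfg$beta0 + bm[.data$month_index] +
        .data$is_intervention * (cfg$beta_arm + bi[.data$month_index]) +
        .data$u + .data$v,
      p_good = plogis(.data$eta),
      good = rbinom(dplyr::n(), 1, .data$p_good) == 1,
      days_missed = ifelse(
        .data$good,
        sample(0:4, dplyr::n(), replace = TRUE),
        5L + rtrunc_geom(dplyr::n(), cfg$missed_geom_prob, 25)
      )
    ) |>
    dplyr::select("participant_id", "clinic_id", "arm", "month_index",
                  "eta", "p_good", "good", "days_missed")

  structure(list(clinics = clinics, participants = participants,
                 truth = truth, config = cfg),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d clinics (%d control), %d participants, %d months\n",
    nrow(x$clinics), sum(x$clinics$arm == "control"),
    nrow(x$participants), x$config$months))
  cat(sprintf("Good participant-months: %.1f%%\n",
              100 * mean(x$truth$good)))
  invisible(x)
}

#' Simulate the device event stream implied by the cohort truth
#'
#' Emits one telemetry record per signal. A 7-day run-in precedes month 1,
#' with several openings per day (the novelty period the first-week exclusion
#' rule exists for). Within each month, the true missed days are placed
#' uniformly at random; taken days emit 1-3 intake signals, non-taken days a
#' heartbeat, and malfunction days (drawn per day at `malfunction_rate`)
#' emit only a "none" signal.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param seed optional integer seed.
#' @return event tibble (`participant_id`, `timestamp`, `signal`) sorted by
#'   participant and time, as [parse_event_log()] would return.
#' @export
simulate_daily_events <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- cohort$config
  truth <- cohort$truth

  run_in <- tidyr::expand_grid(
    participant_id = cohort$participants$participant_id,
    day = seq_len(cfg$run_in_days)
  ) |>
    dplyr::mutate(kind = "taken",
                  n_signals = sample(2:5, dplyr::n(), replace = TRUE))

  month_days <- truth |>
    dplyr::mutate(missed_days = purrr::map(
      .data$days_missed, ~ sample.int(cfg$window_days, .x)
    )) |>
    dplyr::select("participant_id", "month_index", "missed_days") |>
    tidyr::expand_grid(day_in_month = seq_len(cfg$window_days)) |>
    dplyr::mutate(
      day = cfg$run_in_days + (.data$month_index - 1L) * cfg$window_days +
        .data$day_in_month,
      kind = ifelse(purrr::map2_lgl(.data$day_in_month, .data$missed_days,
                                    ~ .x %in% .y),
                    "missed", "taken"),
      n_signals = ifelse(
        .data$kind == "taken",
        sample(1:3, dplyr::n(), replace = TRUE, prob = c(0.7, 0.2, 0.1)),
        1L
      )
    ) |>
    dplyr::select("participant_id", "day", "kind", "n_signals")

  days <- dplyr::bind_rows(run_in, month_days) |>
    dplyr::mutate(
      malfunction = runif(dplyr::n()) < cfg$malfunction_rate,
      kind = ifelse(.data$malfunction, "malfunction", .data$kind),
      n_signals = ifelse(.data$malfunction, 1L, .data$n_signals)
    )

  events <- days |>
    tidyr::uncount(.data$n_signals, .id = "signal_no") |>
    dplyr::mutate(
      signal = dplyr::case_when(
        .data$kind == "taken" ~ "intake",
        .data$kind == "missed" ~ "heartbeat",
        TRUE ~ "none"
      ),
      # first opening around 08:00, repeats later in the day
      secs = ifelse(.data$signal_no == 1,
                    8 * 3600 + round(runif(dplyr::n(), -1800, 1800)),
                    round(runif(dplyr::n(), 10 * 3600, 22 * 3600))),
      timestamp = as.POSIXct(cfg$issue_date, tz = "UTC") +
        (.data$day - 1) * 86400 + .data$secs
    ) |>
    dplyr::select("participant_id", "timestamp", "signal") |>
    dplyr::arrange(.data$participant_id, .data$timestamp) |>
    dplyr::mutate(signal = factor(.data$signal,
                                  levels = c("intake", "heartbeat", "none")))
  events
}

#' Simulate 30-day recall self-reports
#'
#' Self-reported missed days are a binomial thinning of the true missed days
#' (each truly missed day is recalled/admitted with probability
#' `sr_recall_prob`), the simplest mechanism for social-desirability and
#' recall under-reporting. Reported days never exceed true days.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param seed optional integer seed.
#' @return tibble `participant_id`, `month_index`, `days_missed_recall`,
#'   `sr_category`.
#' @export
simulate_self_report <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- cohort$config
  cohort$truth |>
    dplyr::mutate(
      days_missed_recall = rbinom(dplyr::n(), .data$days_missed,
                                  cfg$sr_recall_prob),
      sr_category = dichotomize_sr(.data$days_missed_recall)
    ) |>
    dplyr::select("participant_id", "month_index", "days_missed_recall",
                  "sr_category")
}

#' Simulate month-12 viral loads weakly coupled to adherence
#'
#' Non-suppression probability is `logistic(vl_alpha0 + vl_alpha1 * poor)`
#' using the final month's true adherence category — the timepoint at which
#' the measures are compared. Copy numbers are drawn from a two-component
#' log-uniform mixture on either side of the cutoff, so dichotomizing the
#' continuous value at the cutoff reproduces the binary draw exactly.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param seed optional integer seed.
#' @return tibble `participant_id`, `month_index`, `copies_per_ml`,
#'   `suppressed`.
#' @export
simulate_viral_load <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- cohort$config
  last <- dplyr::filter(cohort$truth, .data$month_index == cfg$months)
  n <- nrow(last)
  p_unsupp <- plogis(cfg$vl_alpha0 + cfg$vl_alpha1 * as.numeric(!last$good))
  unsupp <- rbinom(n, 1, p_unsupp) == 1
  copies <- ifelse(
    unsupp,
    10^runif(n, log10(cfg$vl_cutoff), 5.7),
    10^runif(n, -0.3, log10(cfg$vl_cutoff * 0.98))
  )
  tibble::tibble(
    participant_id = last$participant_id,
    month_index = last$month_index,
    copies_per_ml = copies,
    suppressed = classify_viral_load(copies, cfg$vl_cutoff)
  )
}

#' Simulate a complete synthetic trial
#'
#' Runs the cohort, event, self-report and viral-load generators under one
#' seeded RNG stream. Identical config and seed give identical outputs.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (required: the whole trial must be reproducible).
#' @param out_dir optional directory; when given, writes `events.csv`,
#'   `roster.csv`, `selfreport.csv`, `viral.csv` and `truth.csv`.
#' @return list with `events`, `roster`, `self_report`, `viral_load`,
#'   `truth` (the `cohort_truth` object) and `config`.
#' @export
simulate_trial <- function(cfg = sim_config(), seed, out_dir = NULL) {
  set.seed(seed)
  cohort <- simulate_cohort(cfg)
  events <- simulate_daily_events(cohort)
  sr <- simulate_self_report(cohort)
  vl <- simulate_viral_load(cohort)
  roster <- cohort$participants |>
    dplyr::transmute(
      .data$participant_id, .data$clinic_id, .data$arm,
      issue_date = cfg$issue_date,
      .data$age, .data$age_group, .data$sex
    )
  out <- list(events = events, roster = roster, self_report = sr,
              viral_load = vl, truth = cohort, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(events, file.path(out_dir, "events.csv"))
    readr::write_csv(roster, file.path(out_dir, "roster.csv"))
    readr::write_csv(sr, file.path(out_dir, "selfreport.csv"))
    readr::write_csv(vl, file.path(out_dir, "viral.csv"))
    readr::write_csv(cohort$truth, file.path(out_dir, "truth.csv"))
  }
  out
}
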