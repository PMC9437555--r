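#' Default pipeline configuration
#'
#' Returns the default run configuration as a nested list; [run_pipeline()]
#' merges a user configuration (list or YAML file) over these defaults.
#' Either `simulate` (synthetic trial, the default) or `inputs` (paths to
#' `events`, `roster`, `selfreport`, `viral` CSVs) supplies the data.
#'
#' The comparison analyses (agreement, diagnostic accuracy) are restricted to
#' the control arm by default so measure differences cannot be attributed to
#' the intervention; the trend model always uses both arms.
#'
#' @return nested configuration list.
#' @export
pipeline_defaults <- function() {
  list(
    simulate = list(enabled = TRUE, seed = 1),
    inputs = NULL,
    thresholds = list(missed_threshold = 4, min_observed_days = 15,
                      vl_cutoff = 50),
    sensitivity = list(pct_thresholds = numeric(0), vl_cutoffs = numeric(0)),
    arm_filter = "control",
    bootstrap = list(n_replicates = 1000, seed = 20140101),
    run_trend = TRUE,
    out_dir = NULL
  )
}

# internal: shallow-by-section merge of user config over defaults
merge_config <- function(user, defaults = pipeline_defaults()) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      defaults[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

# internal: month-12 merged analysis dataset
build_merged <- function(monthly, roster, self_report, viral_load, cfg) {
  final_month <- max(monthly$month_index)
  em12 <- monthly |>
    dplyr::filter(.data$month_index == final_month) |>
    dplyr::transmute(
      .data$participant_id,
      em_days_observed = .data$days_observed,
      em_days_missed = .data$days_missed,
      em_category = factor(
        ifelse(.data$category == "unobserved", NA, as.character(.data$category)),
        levels = c("good", "poor")
      )
    )
  sr12 <- self_report |>
    dplyr::filter(.data$month_index == final_month) |>
    dplyr::transmute(.data$participant_id,
                     sr_days_missed = .data$days_missed_recall,
                     sr_category = as_category(.data$sr_category))
  vl12 <- viral_load |>
    dplyr::transmute(.data$participant_id, .data$copies_per_ml,
                     vl_category = viral_load_category(.data$copies_per_ml,
                                                       cfg$thresholds$vl_cutoff))
  roster |>
    dplyr::select(dplyr::any_of(c("participant_id", "clinic_id", "arm",
                                  "age_group", "sex"))) |>
    dplyr::left_join(em12, by = "participant_id") |>
    dplyr::left_join(sr12, by = "participant_id") |>
    dplyr::left_join(vl12, by = "participant_id")
}

#' Sensitivity analyses over dichotomization thresholds
#'
#' Re-runs the diagnostic-accuracy comparison under alternative
#' dichotomizations: percent-adherence thresholds for the adherence measures
#' and alternative viral-load cutoffs, in all combinations with the primary
#' rules.
#'
#' @param merged month-12 merged dataset (see [run_pipeline()]), already
#'   arm-filtered.
#' @param pct_thresholds percent-adherence thresholds (e.g. `c(95, 90, 85)`);
#'   the primary >4-missed-days rule is always included as `"gt4days"`.
#' @param vl_cutoffs viral-load cutoffs in copies/ml; the primary 50 is
#'   always included.
#' @param tests named list mapping a label to the columns used: each entry
#'   `list(days_missed =, days_observed =)`.
#' @return tibble of diagnostic results with `test`, `adherence_rule` and
#'   `vl_cutoff` columns (no bootstrap intervals).
#' @export
threshold_sensitivity <- function(merged,
                                  pct_thresholds = c(95, 90, 85),
                                  vl_cutoffs = c(50, 1000),
                                  tests = list(
                                    em = list(days_missed = "em_days_missed",
                                              days_observed = "em_days_observed"),
                                    sr = list(days_missed = "sr_days_missed",
                                              days_observed = NULL)
                                  )) {
  rules <- c("gt4days", paste0("pct", union(pct_thresholds, numeric(0))))
  cutoffs <- union(50, vl_cutoffs)
  out <- list()
  for (test_name in names(tests)) {
    cols <- tests[[test_name]]
    for (rule in rules) {
      dm <- merged[[cols$days_missed]]
      dobs <- if (is.null(cols$days_observed)) rep(30L, nrow(merged))
              else merged[[cols$days_observed]]
      cat_vec <- if (rule == "gt4days") {
        factor(ifelse(is.na(dm), NA, ifelse(dm > 4, "poor", "good")),
               levels = c("good", "poor"))
      } else {
        pct <- as.numeric(sub("^pct", "", rule))
        ok <- !is.na(dm) & !is.na(dobs) & dobs > 0
        res <- factor(rep(NA_character_, nrow(merged)), levels = c("good", "poor"))
        res[ok] <- percent_adherence_category(dm[ok], dobs[ok], pct)
        res
      }
      for (cut in cutoffs) {
        vl_cat <- viral_load_category(merged$copies_per_ml, cut)
        d <- merged
        d$.test_category <- cat_vec
        d$.vl_category <- vl_cat
        rep <- diagnostic_report(d, test = ".test_category",
                                 outcome = ".vl_category",
                                 n_replicates = 0)
        out[[length(out) + 1]] <- dplyr::bind_cols(
          tibble::tibble(test = test_name, adherence_rule = rule,
                         vl_cutoff = cut),
          rep
        )
      }
    }
  }
  purrr::list_rbind(out)
}

#' Run the full adherence-monitoring pipeline
#'
#' Orchestrates simulate (or load) -> derive monthly adherence -> merge
#' month-12 measures -> agreement report -> diagnostic accuracy -> trend
#' model, deterministically given the configured seeds, and writes plain-CSV
#' outputs plus a run log recording record counts at every stage.
#'
#' @param config a nested list or path to a YAML file; see
#'   [pipeline_defaults()] for the schema and defaults.
#' @return (invisibly) list with `monthly`, `merged`, `comparison` (the
#'   arm-filtered merged data), `table5`, `table6_em`, `table6_sr`,
#'   `roc_em`, `roc_sr`, `trend` (`fit`, `table3`, `margins`, `contrasts`),
#'   `sensitivity`, `log` and `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  log_rows <- list()
  note <- function(stage, n, detail = "") {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, n = as.integer(n), detail = detail)
  }

  # --- stage 1: data --------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate[setdiff(names(cfg$simulate), c("enabled", "seed"))]
    sim_cfg <- do.call(sim_config, sim_args)
    trial <- simulate_trial(sim_cfg, seed = cfg$simulate$seed)
    events <- trial$events
    roster <- trial$roster
    self_report <- trial$self_report
    viral_load <- trial$viral_load
    months <- sim_cfg$months
  } else {
    if (is.null(cfg$inputs)) abort_adh("config must enable simulate or give inputs")
    events <- read_event_log(cfg$inputs$events)
    roster <- readr::read_csv(cfg$inputs$roster, show_col_types = FALSE)
    self_report <- readr::read_csv(cfg$inputs$selfreport, show_col_types = FALSE) |>
      dplyr::mutate(sr_category = dichotomize_sr(.data$days_missed_recall,
                                                 cfg$thresholds$missed_threshold))
    viral_load <- readr::read_csv(cfg$inputs$viral, show_col_types = FALSE)
    months <- cfg$months %||% 12
  }
  note("events", nrow(events), "telemetry signals")
  note("roster", nrow(roster), "participants")

  # --- stage 2: monthly adherence from events -------------------------------
  monthly <- em_monthly(
    events, roster, months = months,
    missed_threshold = cfg$thresholds$missed_threshold,
    min_observed_days = cfg$thresholds$min_observed_days
  )
  note("monthly", nrow(monthly), "participant-months derived")
  note("monthly_classifiable", sum(monthly$category != "unobserved"),
       "participant-months with classifiable adherence")
  note("monthly_unobserved", sum(monthly$category == "unobserved"),
       "participant-months dropped as unobserved")

  # --- stage 3: month-12 merged dataset -------------------------------------
  merged <- build_merged(monthly, roster, self_report, viral_load, cfg)
  note("merged", nrow(merged), "participants in month-12 merged data")

  comparison <- if (identical(cfg$arm_filter, "control")) {
    dplyr::filter(merged, .data$arm == "control")
  } else {
    merged
  }
  note("comparison", nrow(comparison),
       paste0("participants after arm filter '", cfg$arm_filter, "'"))

  # --- stage 4: agreement ----------------------------------------------------
  table5 <- agreement_report(comparison, strata = "age_group")

  # --- stage 5: diagnostic accuracy -----------------------------------------
  table6_em <- diagnostic_report(
    comparison, test = "em_category", strata = "age_group",
    n_replicates = cfg$bootstrap$n_replicates, seed = cfg$bootstrap$seed)
  table6_sr <- diagnostic_report(
    comparison, test = "sr_category", strata = "age_group",
    n_replicates = cfg$bootstrap$n_replicates, seed = cfg$bootstrap$seed)

  cc_em <- dplyr::filter(comparison, !is.na(.data$em_days_missed),
                         !is.na(.data$vl_category))
  roc_em <- auc_model(cc_em$em_days_missed, cc_em$vl_category == "poor")
  cc_sr <- dplyr::filter(comparison, !is.na(.data$sr_days_missed),
                         !is.na(.data$vl_category))
  roc_sr <- auc_model(cc_sr$sr_days_missed, cc_sr$vl_category == "poor")

  # --- stage 6: trend model --------------------------------------------------
  trend <- NULL
  if (isTRUE(cfg$run_trend)) {
    trend_data <- monthly |>
      dplyr::left_join(
        dplyr::select(roster, "participant_id", "clinic_id", "arm"),
        by = "participant_id") |>
      dplyr::mutate(good = dplyr::case_when(
        .data$category == "good" ~ TRUE,
        .data$category == "poor" ~ FALSE,
        TRUE ~ NA
      ))
    note("trend_observations", sum(!is.na(trend_data$good)),
         "participant-months entering the trend model")
    fit <- fit_adherence_trend(trend_data)
    trend <- list(
      fit = fit,
      table3 = fit$coefficients,
      varcomp = tibble::tibble(component = names(fit$varcomp),
                               variance = unname(fit$varcomp)),
      margins = marginal_predictions(fit),
      contrasts = time_contrasts(fit)
    )
  }

  # --- stage 7: threshold sensitivity ---------------------------------------
  sensitivity <- NULL
  if (length(cfg$sensitivity$pct_thresholds) > 0 ||
      length(cfg$sensitivity$vl_cutoffs) > 0) {
    sensitivity <- threshold_sensitivity(
      comparison,
      pct_thresholds = cfg$sensitivity$pct_thresholds,
      vl_cutoffs = cfg$sensitivity$vl_cutoffs)
  }

  log <- purrr::list_rbind(log_rows)
  result <- list(
    monthly = monthly, merged = merged, comparison = comparison,
    table5 = table5, table6_em = table6_em, table6_sr = table6_sr,
    roc_em = roc_em, roc_sr = roc_sr, trend = trend,
    sensitivity = sensitivity, log = log, config = cfg,
    # hash identifies the analysis, not where its files land
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  )

  # --- stage 8: outputs ------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) readr::write_csv(x, file.path(cfg$out_dir, name))
    w(monthly, "monthly.csv")
    w(merged, "merged.csv")
    w(table5, "table5.csv")
    w(table6_em, "table6_em.csv")
    w(table6_sr, "table6_sr.csv")
    w(roc_em$roc_points, "roc_em.csv")
    w(roc_sr$roc_points, "roc_sr.csv")
    if (!is.null(trend)) {
      w(trend$table3, "table3_coefficients.csv")
      w(trend$varcomp, "table3_varcomp.csv")
      w(trend$margins, "margins.csv")
      w(trend$contrasts$contrasts, "contrasts.csv")
    }
    if (!is.null(sensitivity)) w(sensitivity, "table6_sensitivity.csv")
    writeLines(
      c(sprintf("config_hash: %s", result$config_hash),
        sprintf("%-24s %8d  %s", log$stage, log$n, log$detail)),
      file.path(cfg$out_dir, "run_log.txt"))
  }
  invisible(result)
}
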