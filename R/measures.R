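#' Dichotomize self-reported missed days
#'
#' The self-report instrument asks "In the last 30 days, on how many days did
#' you miss at least one dose of your HIV medications?". Recall counts are
#' dichotomized with the same >`threshold` days/month rule used for
#' electronic monitoring: more than 4 missed days is poor adherence.
#'
#' @param days_missed_recall integer vector of recalled missed days, 0..30
#'   (NA allowed and propagated).
#' @param threshold maximum missed days compatible with good adherence,
#'   default 4.
#' @return factor with levels `good`, `poor`.
#' @examples
#' dichotomize_sr(c(0, 4, 5, 30))
#' @export
dichotomize_sr <- function(days_missed_recall, threshold = 4) {
  ok <- is.na(days_missed_recall) |
    (days_missed_recall >= 0 & days_missed_recall <= 30)
  if (!all(ok)) {
    abort_adh("days_missed_recall must be within 0..30; offending value(s): ",
              paste(head(days_missed_recall[!ok], 5), collapse = ", "))
  }
  factor(ifelse(days_missed_recall > threshold, "poor", "good"),
         levels = c("good", "poor"))
}

#' Classify viral load as suppressed
#'
#' Suppression uses a strict inequality: a measurement exactly at the cutoff
#' is unsuppressed. The primary cutoff is 50 copies/ml; 1000 copies/ml is the
#' national-guideline alternative used in sensitivity analyses.
#'
#' @param copies_per_ml non-negative numeric vector (NA propagated).
#' @param cutoff suppression cutoff in copies/ml, default 50.
#' @return logical vector, `TRUE` = suppressed.
#' @examples
#' classify_viral_load(c(0, 49, 50, 999), cutoff = 50)
#' @export
classify_viral_load <- function(copies_per_ml, cutoff = 50) {
  if (any(copies_per_ml < 0, na.rm = TRUE)) {
    abort_adh("viral load cannot be negative")
  }
  copies_per_ml < cutoff
}

#' Dichotomize adherence by a percent-adherence threshold
#'
#' Alternative dichotomization used in sensitivity analyses: good adherence
#' means at least `pct` percent of observed days had a dose taken. On a full
#' 30-day window, the >4-missed-days rule is equivalent to a percent threshold
#' strictly between 83.4% and 86.6%.
#'
#' @param days_missed integer vector of missed days.
#' @param days_observed integer vector of observed (classifiable) days,
#'   0 < days_observed <= 30.
#' @param pct percent-adherence threshold in (0, 100].
#' @return factor with levels `good`, `poor`.
#' @examples
#' percent_adherence_category(1, 30, 95) # 96.7% adherent -> good
#' percent_adherence_category(2, 30, 95) # 93.3% adherent -> poor
#' @export
percent_adherence_category <- function(days_missed, days_observed, pct) {
  stopifnot(pct > 0, pct <= 100)
  if (any(days_observed <= 0 | days_observed > 30, na.rm = TRUE)) {
    abort_adh("days_observed must be in 1..30")
  }
  if (any(days_missed > days_observed, na.rm = TRUE)) {
    abort_adh("days_missed cannot exceed days_observed")
  }
  adherent <- (days_observed - days_missed) / days_observed * 100
  factor(ifelse(adherent >= pct, "good", "poor"), levels = c("good", "poor"))
}

#' Viral-load category on the adherence scale
#'
#' Recodes suppression to the shared `good`/`poor` category scale so viral
#' load can be cross-classified with the adherence measures: unsuppressed
#' maps to `poor` (the "positive" category), suppressed to `good`.
#'
#' @inheritParams classify_viral_load
#' @return factor with levels `good`, `poor`.
#' @export
viral_load_category <- function(copies_per_ml, cutoff = 50) {
  factor(ifelse(classify_viral_load(copies_per_ml, cutoff), "good", "poor"),
         levels = c("good", "poor"))
}
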