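#' Sensitivity and specificity of poor adherence for viral non-suppression
#'
#' Treats poor adherence (measure A, category 1) as a diagnostic "positive"
#' for viral non-suppression (measure B, category 1 = case). With that
#' orientation the cells of the [two_by_two()] table are TP = n11, FP = n10,
#' FN = n01, TN = n00. Wilson score 95% intervals are attached; for a single
#' binary test the implied AUC is `(sensitivity + specificity) / 2`.
#'
#' @param t a [two_by_two()] table oriented test-vs-outcome.
#' @param conf confidence level for the Wilson intervals, default 0.95.
#' @return list with `sensitivity`, `specificity` (each a Wilson
#'   `estimate`/`lower`/`upper` vector), `auc`, `n_cases`, `n_controls`.
#' @examples
#' sens_spec(two_by_two(19, 33, 64, 135)) # EM: sens 22.9%, spec 80.4%
#' @export
sens_spec <- function(t, conf = 0.95) {
  n_cases <- t$n11 + t$n01
  n_controls <- t$n10 + t$n00
  if (n_cases == 0) abort_adh("no cases (non-suppressed) in the table")
  if (n_controls == 0) abort_adh("no controls (suppressed) in the table")
  sens <- wilson_ci(t$n11, n_cases, conf)
  spec <- wilson_ci(t$n00, n_controls, conf)
  list(
    sensitivity = sens, specificity = spec,
    auc = unname((sens["estimate"] + spec["estimate"]) / 2),
    n_cases = n_cases, n_controls = n_controls
  )
}

#' AUC of a dichotomous test
#'
#' For a binary marker the area under the ROC curve equals the Mann–Whitney
#' probability that a random case scores higher than a random control (ties
#' counted half), which reduces to `(sensitivity + specificity) / 2`. The
#' orientation is fixed — poor adherence predicts non-suppression — and is
#' never flipped to force AUC above 0.5.
#'
#' @inheritParams sens_spec
#' @return the AUC as a proportion.
#' @export
auc_binary <- function(t) {
  sens_spec(t)$auc
}

#' Empirical ROC curve and AUC for a continuous adherence score
#'
#' Builds the empirical ROC over all thresholds of a continuous score (e.g.
#' missed days, where higher means worse adherence) against a binary outcome,
#' with AUC by the trapezoid rule (equivalently the tie-corrected
#' Mann–Whitney statistic). The ROC step curve is computed by \pkg{pROC};
#' points are returned for plotting.
#'
#' @param score numeric score, higher values indicating the case state.
#' @param case logical outcome, `TRUE` = case (non-suppressed).
#' @return list with `auc` and `roc_points` (tibble `threshold`, `fpr`,
#'   `tpr`). A constant score yields AUC 0.5 with a warning.
#' @export
auc_model <- function(score, case) {
  if (length(score) != length(case)) abort_adh("score and case must have equal length")
  keep <- !is.na(score) & !is.na(case)
  score <- score[keep]
  case <- as.logical(case[keep])
  if (!any(case) || all(case)) abort_adh("need at least one case and one control")
  if (length(unique(score)) == 1) {
    warning("degenerate (constant) score: AUC is 0.5 by convention")
    return(list(
      auc = 0.5,
      roc_points = tibble::tibble(threshold = NA_real_, fpr = c(0, 1), tpr = c(0, 1))
    ))
  }
  r <- pROC::roc(response = case, predictor = score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(
    auc = as.numeric(pROC::auc(r)),
    roc_points = tibble::tibble(
      threshold = rev(r$thresholds),
      fpr = rev(1 - r$specificities),
      tpr = rev(r$sensitivities)
    )
  )
}

#' Clinic-level cluster bootstrap confidence interval
#'
#' Resamples whole clinics with replacement (the same number of clinics as
#' observed, keeping every row of each drawn clinic, with duplication) and
#' returns percentile bounds of the statistic over the replicates. Resampling
#' the randomization unit respects intra-clinic correlation. Replicates on
#' which the statistic is undefined (e.g. a resample with no cases) are
#' redrawn and counted.
#'
#' @param data data frame with a cluster id column.
#' @param statistic function of a data frame returning a single number.
#' @param cluster name of the cluster id column, default `"clinic_id"`.
#' @param n_replicates bootstrap replicates, default 1000.
#' @param seed optional integer seed for reproducibility.
#' @param conf confidence level, default 0.95.
#' @return list with `lower`, `upper`, `replicates` (the bootstrap values)
#'   and `n_redraws`.
#' @export
cluster_bootstrap_ci <- function(data, statistic, cluster = "clinic_id",
                                 n_replicates = 1000, seed = NULL, conf = 0.95) {
  stopifnot(n_replicates >= 1)
  if (!cluster %in% names(data)) abort_adh("no column '", cluster, "' in data")
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(data[[cluster]])
  if (length(ids) < 2) abort_adh("cluster bootstrap needs at least 2 clinics")
  rows_by_id <- split(seq_len(nrow(data)), data[[cluster]])
  reps <- numeric(n_replicates)
  n_redraws <- 0L
  max_attempts <- 100L * n_replicates
  for (b in seq_len(n_replicates)) {
    repeat {
      draw <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(rows_by_id[as.character(draw)], use.names = FALSE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (length(val) == 1 && is.finite(val)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_attempts) {
        abort_adh("statistic undefined on too many bootstrap replicates")
      }
    }
    reps[b] <- val
  }
  alpha <- (1 - conf) / 2
  bounds <- unname(quantile(reps, c(alpha, 1 - alpha), names = FALSE))
  list(lower = bounds[1], upper = bounds[2], replicates = reps,
       n_redraws = n_redraws)
}

#' Diagnostic-accuracy report for an adherence measure
#'
#' Produces the counts, specificity, sensitivity (Wilson intervals) and AUC
#' with clinic-level cluster-bootstrap interval for one adherence measure as
#' a predictor of viral non-suppression, overall and optionally by stratum.
#'
#' @param data one row per participant with category columns (levels
#'   `good`/`poor`) and a cluster id column.
#' @param test name of the adherence category column (default EM).
#' @param outcome name of the viral-load category column (`poor` =
#'   unsuppressed).
#' @param strata optional stratification column name; `"overall"` always
#'   included.
#' @param score optional name of a continuous score column (e.g. missed
#'   days); when given, the model-based AUC of [auc_model()] is reported,
#'   otherwise the binary-test AUC.
#' @param cluster cluster id column for the bootstrap, default `"clinic_id"`.
#' @param n_replicates,seed bootstrap settings (see
#'   [cluster_bootstrap_ci()]); `n_replicates = 0` skips the AUC interval.
#' @return tibble, one row per stratum: cell counts, sensitivity and
#'   specificity with Wilson bounds, and AUC with bootstrap bounds.
#' @export
diagnostic_report <- function(data, test = "em_category", outcome = "vl_category",
                              strata = NULL, score = NULL,
                              cluster = "clinic_id", n_replicates = 1000,
                              seed = NULL) {
  groups <- list(overall = rep(TRUE, nrow(data)))
  if (!is.null(strata)) {
    for (lev in sort(unique(as.character(data[[strata]])))) {
      groups[[lev]] <- !is.na(data[[strata]]) & data[[strata]] == lev
    }
  }
  auc_of <- function(d) {
    if (is.null(score)) {
      auc_binary(cross_classify(d[[test]], d[[outcome]]))
    } else {
      auc_model(d[[score]], as_category(d[[outcome]]) == "poor")$auc
    }
  }
  purrr::map(names(groups), function(g) {
    sub <- data[groups[[g]], , drop = FALSE]
    t_ss <- tryCatch({
      t <- cross_classify(sub[[test]], sub[[outcome]])
      list(t = t, ss = sens_spec(t))
    }, error = function(e) NULL)
    if (is.null(t_ss)) {
      warning(sprintf("stratum '%s': degenerate table, skipped", g))
      return(NULL)
    }
    t <- t_ss$t
    ss <- t_ss$ss
    auc <- auc_of(sub)
    ci <- if (n_replicates > 0) {
      cluster_bootstrap_ci(sub, auc_of, cluster = cluster,
                           n_replicates = n_replicates, seed = seed)
    } else {
      list(lower = NA_real_, upper = NA_real_)
    }
    tibble::tibble(
      stratum = g, n = t$n,
      tp = t$n11, fp = t$n10, fn = t$n01, tn = t$n00,
      sensitivity = ss$sensitivity[["estimate"]],
      sens_lower = ss$sensitivity[["lower"]],
      sens_upper = ss$sensitivity[["upper"]],
      specificity = ss$specificity[["estimate"]],
      spec_lower = ss$specificity[["lower"]],
      spec_upper = ss$specificity[["upper"]],
      auc = auc, auc_lower = ci$lower, auc_upper = ci$upper
    )
  }) |>
    purrr::list_rbind()
}
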