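test_that("sensitivity and specificity reproduce the published accuracy values", {
  # electronic monitoring vs viral load, control arm, month 12
  em <- sens_spec(two_by_two(19, 33, 64, 135))
  expect_equal(round(100 * em$sensitivity[["estimate"]], 1), 22.9)
  expect_equal(round(100 * em$specificity[["estimate"]], 1), 80.4)
  expect_equal(em$n_cases, 83)
  expect_equal(em$n_controls, 168)

  sr <- sens_spec(two_by_two(2, 7, 111, 208))
  expect_equal(round(100 * sr$sensitivity[["estimate"]], 1), 1.8)
  expect_equal(round(100 * sr$specificity[["estimate"]], 1), 96.7)

  perfect <- sens_spec(two_by_two(10, 0, 0, 20))
  expect_equal(perfect$sensitivity[["estimate"]], 1)
  expect_equal(perfect$specificity[["estimate"]], 1)

  expect_error(sens_spec(two_by_two(0, 5, 0, 10)), "cases")
  expect_error(sens_spec(two_by_two(5, 0, 10, 0)), "controls")
})

test_that("Wilson intervals are proper and match the score-test inversion", {
  grid <- expand.grid(x = c(0, 1, 5, 19, 135), n = c(5, 50, 168))
  grid <- grid[grid$x <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    ci <- wilson_ci(grid$x[i], grid$n[i])
    expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
    expect_true(ci[["lower"]] <= ci[["estimate"]] &&
                  ci[["estimate"]] <= ci[["upper"]])
    # independent route: stats::prop.test without continuity correction
    # inverts the same score test
    pt <- suppressWarnings(prop.test(grid$x[i], grid$n[i], correct = FALSE))
    expect_equal(unname(ci[c("lower", "upper")]), as.numeric(pt$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("binary-test AUC equals the Mann-Whitney probability over all pairs", {
  expect_equal(auc_binary(two_by_two(19, 33, 64, 135)), (19/83 + 135/168) / 2)
  expect_equal(auc_binary(two_by_two(5, 10, 5, 10)), 0.5) # uninformative test
  set.seed(21)
  for (i in 1:15) {
    t <- random_table(50)
    # oracle: enumerate every case-control pair with the 0/1 score, ties = 1/2
    case_scores <- rep(c(1, 0), c(t$n11, t$n01))
    control_scores <- rep(c(1, 0), c(t$n10, t$n00))
    wins <- outer(case_scores, control_scores, ">")
    ties <- outer(case_scores, control_scores, "==")
    expect_equal(auc_binary(t), mean(wins + 0.5 * ties))
    # and auc_model on the dichotomized 0/1 score agrees
    score <- c(case_scores, control_scores)
    case <- rep(c(TRUE, FALSE), c(length(case_scores), length(control_scores)))
    if (length(unique(score)) > 1) {
      expect_equal(auc_model(score, case)$auc, auc_binary(t))
    }
  }
})

test_that("empirical ROC AUC matches pair enumeration and its invariances", {
  expect_equal(auc_model(c(3, 5, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(auc_model(c(0, 2, 5, 0, 1, 4),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               (5 + 0.5) / 9)
  expect_warning(
    const <- auc_model(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    "constant"
  )
  expect_equal(const$auc, 0.5)

  set.seed(22)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    score <- sample(0:8, n, replace = TRUE)
    case <- runif(n) < 0.4
    if (!any(case) || all(case) || length(unique(score)) == 1) next
    a <- auc_model(score, case)$auc
    wins <- outer(score[case], score[!case], ">")
    ties <- outer(score[case], score[!case], "==")
    expect_equal(a, mean(wins + 0.5 * ties))
    # monotone transform leaves AUC unchanged; flipping orientation maps a -> 1-a
    expect_equal(auc_model(exp(score / 3), case)$auc, a)
    expect_equal(auc_model(-score, case)$auc, 1 - a, tolerance = 1e-10)
  }
})

test_that("cluster bootstrap is deterministic, degenerate-safe, and covers the estimate", {
  # two clinics with identical data: every resample gives the same statistic
  d <- tibble::tibble(clinic_id = rep(c("A", "B"), each = 4), y = rep(c(1, 0, 1, 1), 2))
  ci <- cluster_bootstrap_ci(d, function(x) mean(x$y), n_replicates = 50, seed = 1)
  expect_equal(ci$lower, mean(d$y))
  expect_equal(ci$upper, mean(d$y))

  # fixed seed -> identical bounds
  set.seed(31)
  d2 <- tibble::tibble(
    clinic_id = rep(sprintf("C%02d", 1:19), each = 10),
    case = runif(190) < 0.3, positive = runif(190) < 0.25
  )
  stat <- function(x) {
    if (!any(x$case) || !any(!x$case)) stop("empty margin")
    sum(x$positive & x$case) / sum(x$case)
  }
  r1 <- cluster_bootstrap_ci(d2, stat, n_replicates = 200, seed = 99)
  r2 <- cluster_bootstrap_ci(d2, stat, n_replicates = 200, seed = 99)
  expect_equal(r1$lower, r2$lower)
  expect_equal(r1$upper, r2$upper)

  # the interval contains the point estimate
  point <- stat(d2)
  expect_true(r1$lower <= point && point <= r1$upper)

  expect_error(cluster_bootstrap_ci(d2[d2$clinic_id == "C01", ], stat),
               "at least 2")
})

test_that("replicates with an undefined statistic are redrawn and counted", {
  # only one of three clinics has any cases, so many resamples miss all cases
  d <- tibble::tibble(
    clinic_id = rep(c("A", "B", "C"), each = 5),
    case = rep(c(TRUE, FALSE, FALSE), each = 5),
    positive = rep(c(TRUE, FALSE, FALSE), each = 5)
  )
  stat <- function(x) {
    if (!any(x$case)) stop("no cases")
    mean(x$positive[x$case])
  }
  r <- cluster_bootstrap_ci(d, stat, n_replicates = 100, seed = 5)
  expect_gt(r$n_redraws, 0)
  expect_true(all(is.finite(r$replicates)))
})

test_that("the diagnostic report carries counts, accuracy and AUC per stratum", {
  set.seed(41)
  n <- 240
  d <- tibble::tibble(
    clinic_id = sample(sprintf("C%02d", 1:12), n, TRUE),
    em_category = sample(c("good", "poor"), n, TRUE, prob = c(0.8, 0.2)),
    vl_category = sample(c("good", "poor"), n, TRUE, prob = c(0.65, 0.35)),
    age_group = sample(c("10-13", "14-16"), n, TRUE)
  )
  rep <- diagnostic_report(d, strata = "age_group", n_replicates = 50, seed = 3)
  expect_equal(rep$stratum, c("overall", "10-13", "14-16"))
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, rep$n)
  expect_true(all(rep$auc_lower <= rep$auc & rep$auc <= rep$auc_upper))
  # the dichotomous AUC equals (sens+spec)/2 row by row
  expect_equal(rep$auc, (rep$sensitivity + rep$specificity) / 2)
})
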