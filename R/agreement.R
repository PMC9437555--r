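#' A 2x2 cross-classification of two binary measures
#'
#' Cell `n11` counts pairs where both measures are in category 1
#' ("poor"/"unsuppressed"), `n10` where only measure A is, `n01` where only
#' measure B is, `n00` where neither is.
#'
#' @param n11,n10,n01,n00 non-negative integer cell counts; the total must be
#'   positive.
#' @return an object of class `two_by_two`.
#' @examples
#' # viral load (B) vs electronic monitoring (A), control arm, month 12:
#' two_by_two(n11 = 19, n10 = 33, n01 = 64, n00 = 135)
#' @export
two_by_two <- function(n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_adh("cell counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n <= 0) abort_adh("a two_by_two table needs at least one observation")
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = n),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2, 2,
              dimnames = list(A = c("poor", "good"), B = c("poor", "good")))
  cat("2x2 cross-classification (n = ", x$n, ")\n", sep = "")
  print(m)
  invisible(x)
}

# internal: marginal proportions of the "1" (poor/unsuppressed) category
marginals_1 <- function(t) {
  c(pA1 = (t$n11 + t$n10) / t$n, pB1 = (t$n11 + t$n01) / t$n)
}

#' Cross-classify two categorical measures
#'
#' Pairs with a missing value in either measure are dropped (listwise
#' deletion); the number dropped is attached as attribute `n_dropped`. This
#' means each measure pair uses its own complete-case n.
#'
#' @param a,b equal-length vectors with values `"good"`/`"poor"` (factors or
#'   character; NA allowed).
#' @return a [two_by_two()] table; `"poor"` is category 1.
#' @export
cross_classify <- function(a, b) {
  if (length(a) != length(b)) abort_adh("measures must have equal length")
  a <- as_category(a)
  b <- as_category(b)
  complete <- !is.na(a) & !is.na(b)
  if (!any(complete)) abort_adh("no complete pairs to cross-classify")
  a <- a[complete]
  b <- b[complete]
  t <- two_by_two(
    n11 = sum(a == "poor" & b == "poor"),
    n10 = sum(a == "poor" & b == "good"),
    n01 = sum(a == "good" & b == "poor"),
    n00 = sum(a == "good" & b == "good")
  )
  attr(t, "n_dropped") <- sum(!complete)
  t
}

#' Observed proportion of agreement
#'
#' @param t a [two_by_two()] table.
#' @return Pa = (n11 + n00) / n.
#' @export
observed_agreement <- function(t) {
  (t$n11 + t$n00) / t$n
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance agreement is the marginal product `Pe = pA1*pB1 + pA0*pB0`; kappa is
#' the observed agreement corrected for it, `(Pa - Pe) / (1 - Pe)`. Under
#' skewed marginals kappa can be near zero despite high observed agreement
#' (the "kappa paradox"); see [gwet_ac1()] for the paradox-adjusted
#' coefficient. Kappa is reported signed.
#'
#' @param t a [two_by_two()] table.
#' @return list with `pa`, `pe` and `kappa` (`kappa` is NA with a warning if
#'   the marginals are degenerate, Pe = 1).
#' @examples
#' cohen_kappa(two_by_two(19, 33, 64, 135)) # kappa ~ 0.036
#' @export
cohen_kappa <- function(t) {
  pa <- observed_agreement(t)
  m <- marginals_1(t)
  pe <- m["pA1"] * m["pB1"] + (1 - m["pA1"]) * (1 - m["pB1"])
  pe <- unname(pe)
  if (pe >= 1) {
    warning("degenerate marginals: chance agreement is 1, kappa undefined")
    return(list(pa = pa, pe = pe, kappa = NA_real_))
  }
  list(pa = pa, pe = pe, kappa = (pa - pe) / (1 - pe))
}

#' Gwet's AC1 for a 2x2 table
#'
#' Gwet's first-order agreement coefficient replaces kappa's marginal-product
#' chance term with `Pe_gamma = 2 * pi * (1 - pi)`, where `pi` is the mean of
#' the two marginal "poor" proportions (the K-category form is
#' `(1/(K-1)) * sum_k pi_k (1 - pi_k)`). Under skewed marginals `Pe_gamma`
#' shrinks instead of inflating, which corrects the kappa paradox.
#'
#' @param t a [two_by_two()] table.
#' @return list with `pa`, `pe_gamma` and `ac1` (NA with a warning if
#'   `Pe_gamma` = 1).
#' @examples
#' gwet_ac1(two_by_two(2, 7, 111, 208)) # AC1 ~ 0.484
#' @export
gwet_ac1 <- function(t) {
  pa <- observed_agreement(t)
  m <- marginals_1(t)
  pi1 <- unname((m["pA1"] + m["pB1"]) / 2)
  pe_gamma <- 2 * pi1 * (1 - pi1)
  if (pe_gamma >= 1) {
    warning("degenerate marginals: adjusted chance agreement is 1, AC1 undefined")
    return(list(pa = pa, pe_gamma = pe_gamma, ac1 = NA_real_))
  }
  list(pa = pa, pe_gamma = pe_gamma, ac1 = (pa - pe_gamma) / (1 - pe_gamma))
}

# internal: one row of agreement statistics for a table
agreement_row <- function(t) {
  k <- cohen_kappa(t)
  g <- gwet_ac1(t)
  tibble::tibble(
    n = t$n, n_dropped = attr(t, "n_dropped") %||% 0L,
    pa = k$pa, pe = k$pe, pe_gamma = g$pe_gamma,
    kappa = k$kappa, ac1 = g$ac1
  )
}

#' Agreement report across measure pairs and strata
#'
#' Computes observed agreement, kappa chance agreement, AC1-adjusted chance
#' agreement, kappa and AC1 for every pair of measure columns, overall and
#' within each level of an optional stratification column (e.g. age group).
#'
#' @param data a data frame holding one row per participant and one
#'   `good`/`poor` category column per measure.
#' @param measures character vector of category column names; all pairs are
#'   compared. Default the electronic-monitoring, self-report and viral-load
#'   columns produced by the pipeline.
#' @param strata optional name of a stratification column; the `"overall"`
#'   stratum is always included. Strata with no complete pairs for a given
#'   measure pair are skipped with a warning.
#' @return tibble with one row per (pair, stratum).
#' @export
agreement_report <- function(data,
                             measures = c("vl_category", "em_category", "sr_category"),
                             strata = NULL) {
  pairs <- utils::combn(measures, 2, simplify = FALSE)
  groups <- list(overall = rep(TRUE, nrow(data)))
  if (!is.null(strata)) {
    for (lev in sort(unique(as.character(data[[strata]])))) {
      groups[[lev]] <- !is.na(data[[strata]]) & data[[strata]] == lev
    }
  }
  out <- list()
  for (g in names(groups)) {
    sub <- data[groups[[g]], , drop = FALSE]
    for (p in pairs) {
      t <- tryCatch(cross_classify(sub[[p[1]]], sub[[p[2]]]),
                    error = function(e) NULL)
      if (is.null(t)) {
        warning(sprintf("stratum '%s': no complete pairs for %s vs %s; skipped",
                        g, p[1], p[2]))
        next
      }
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(pair = paste(p[1], "vs", p[2]), stratum = g),
        agreement_row(t)
      )
    }
  }
  purrr::list_rbind(out)
}
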