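#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval inverts the score test for a binomial proportion. It is
#' never outside \[0, 1\] and always contains the point estimate x/n, which the
#' Wald interval does not guarantee near the boundaries — relevant here because
#' adherence sensitivities can sit very close to 0.
#'
#' @param x number of successes (non-negative integer).
#' @param n number of trials (positive integer, `x <= n`).
#' @param conf confidence level, default 0.95.
#' @return named numeric vector with `estimate`, `lower`, `upper`.
#' @examples
#' wilson_ci(135, 168) # specificity of electronic monitoring vs viral load
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n > 0, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the interval provably contains p; min/max guard floating-point round-off
  # at the boundaries (x = 0 or x = n)
  c(estimate = p,
    lower = min(p, max(0, centre - half)),
    upper = max(p, min(1, centre + half)))
}

# internal: stop without the call, with a consistent prefix
abort_adh <- function(...) stop(..., call. = FALSE)

# internal: coerce an adherence category vector to factor(good, poor)
as_category <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), c("good", "poor"))
  if (length(bad) > 0) {
    abort_adh("unknown adherence category label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = c("good", "poor"))
}
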