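#' Exact binomial test
#'
#' Tail probability of observing `k` successes in `n` Bernoulli trials with
#' success probability `p0`. The two-sided p-value follows the minimum-
#' likelihood convention: it sums the probabilities of every outcome whose
#' point probability does not exceed that of the observed outcome. This is
#' the convention under which a 12-of-13 split against an even null gives
#' p = 0.0034.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability, strictly inside (0, 1).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#'
#' @return A [`comp_test`][new_comp_test] with `statistic = k`.
#' @examples
#' binom_exact(12, 13)$p_value # 0.0034
#' @export
binom_exact <- function(k, n, p0 = 0.5, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  if (length(n) != 1L || is.na(n) || n < 1) abort("n must be a count >= 1")
  if (length(k) != 1L || is.na(k) || k < 0 || k > n) abort("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly inside (0, 1)")
  k <- as.integer(k); n <- as.integer(n)
  p <- switch(alternative,
    less = pbinom(k, n, p0),
    greater = pbinom(k - 1L, n, p0, lower.tail = FALSE),
    two_sided = {
      # minlike: sum pmf over outcomes no more likely than the observed one,
      # with a small relative tolerance against FP noise
      pk <- dbinom(k, n, p0)
      pmf <- dbinom(0:n, n, p0)
      sum(pmf[pmf <= pk * (1 + 1e-7)])
    })
  new_comp_test(statistic = k, p_value = min(1, p),
                method = "exact binomial test", alternative = alternative,
                n = n, p0 = p0)
}

#' One-sample proportion test with continuity correction
#'
#' Chi-square test of a single proportion against `p0` with Yates'
#' continuity correction, `(|k - n p0| - 1/2)^2 / (n p0 (1 - p0))`. The
#' correction is truncated so it never overshoots the observed deviation.
#' One-sided p-values take the corresponding normal tail in the direction of
#' the alternative. This is the large-sample companion to [binom_exact()]:
#' a one-sided test of 13 successes in 15 trials against 0.5 gives p = 0.005.
#'
#' @inheritParams binom_exact
#' @return A [`comp_test`][new_comp_test] with the chi-square statistic
#'   (`df = 1`).
#' @examples
#' prop_test_cc(10, 13, alternative = "greater")$p_value # 0.048
#' @export
prop_test_cc <- function(k, n, p0 = 0.5, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  if (length(n) != 1L || is.na(n) || n < 1) abort("n must be a count >= 1")
  if (length(k) != 1L || is.na(k) || k < 0 || k > n) abort("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly inside (0, 1)")
  expected <- n * p0
  cc <- min(0.5, abs(k - expected)) # truncate rather than overshoot
  stat <- (abs(k - expected) - cc)^2 / (n * p0 * (1 - p0))
  z <- sign(k - expected) * sqrt(stat)
  p <- switch(alternative,
    two_sided = pchisq(stat, df = 1, lower.tail = FALSE),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z))
  new_comp_test(statistic = stat, p_value = p,
                method = "1-sample proportion test with continuity correction",
                alternative = alternative, n = n, p0 = p0, df = 1L)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons `m` and truncates
#' at 1.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of comparisons; must be at least `length(p_values)`.
#'   Defaults to the length of the input.
#' @return Adjusted p-values, same length as the input.
#' @examples
#' bonferroni_adjust(c(0.001, 0.04), m = 3)
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) abort("m must be >= length(p_values)")
  pmin(1, p_values * m)
}
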