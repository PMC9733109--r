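# Exact null distributions for the rank tests are built by dynamic
# programming rather than taken from closed forms, so that the permutation
# conventions (min-U reporting, minlike two-sided doubling) are explicit.

# Counts of the rank-sum distribution: number of ways to pick `m` of the
# ranks 1..(m+n) achieving each possible rank sum. Column s+1 holds sum s.
ranksum_counts <- function(m, n) {
  total <- m + n
  maxsum <- sum((n + 1):total) # largest achievable rank sum for m ranks
  f <- matrix(0, nrow = m + 1L, ncol = maxsum + 1L)
  f[1L, 1L] <- 1
  for (r in seq_len(total)) {
    jmax <- min(m, r)
    for (j in jmax:1) {
      # add rank r to subsets of size j-1
      src <- f[j, ]
      shifted <- c(rep(0, r), src[seq_len(length(src) - r)])
      f[j + 1L, ] <- f[j + 1L, ] + shifted
    }
  }
  f[m + 1L, ]
}

# Counts of the signed-rank statistic V = sum of positive ranks over all
# 2^n sign assignments of integer ranks 1..n.
signedrank_counts <- function(n) {
  maxv <- n * (n + 1L) / 2L
  f <- numeric(maxv + 1L)
  f[1L] <- 1
  for (r in seq_len(n)) {
    f <- f + c(rep(0, r), f[seq_len(maxv + 1L - r)])
  }
  f
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test reporting both the U statistic for the first
#' sample and the smaller of the two U values (the statistic conventionally
#' printed as W). The null distribution is exact -- computed by dynamic
#' programming over all rank assignments -- whenever both samples have at
#' most 20 observations and no ties are present; otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or `"less"`.
#' @return A [`comp_test`][new_comp_test] whose `statistic` is
#'   `min(U, nm - U)`; field `u_x` holds the U of `x`.
#' @export
mann_whitney <- function(x, y, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be nonempty")
  if (anyNA(c(x, y))) abort("missing values are not supported")
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_x <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  u_min <- min(u_x, nx * ny - u_x)
  ties <- table(ranks)
  has_ties <- any(ties > 1L)
  if (length(unique(c(x, y))) == 1L) {
    warn("all values identical across both samples; p = 1")
    return(new_comp_test(u_min, 1, "Mann-Whitney rank-sum test (degenerate)",
                         alternative, u_x = u_x, exact = FALSE))
  }
  exact <- !has_ties && nx <= 20L && ny <= 20L
  if (exact) {
    counts <- ranksum_counts(nx, ny)
    offset <- nx * (nx + 1) / 2 # rank sum -> U
    total <- sum(counts)
    probs <- counts / total
    uvals <- seq_along(counts) - 1 - offset
    p_le <- sum(probs[uvals <= u_x])
    p_ge <- sum(probs[uvals >= u_x])
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two_sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact Mann-Whitney rank-sum test"
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma <- sqrt(nx * ny / 12 * (nx + ny + 1 - tie_term))
    z <- u_x - mu
    cc <- switch(alternative, two_sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two_sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))))
    method <- "Mann-Whitney rank-sum test (normal approximation)"
  }
  new_comp_test(u_min, p, method, alternative,
                u_x = u_x, n_x = nx, n_y = ny, exact = exact)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' V is the sum of the ranks of the positive differences `x - y`; zero
#' differences are dropped (their number is recorded). The null
#' distribution is exact -- a sign-flip enumeration by dynamic programming --
#' for up to 25 nonzero untied differences, and a tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Paired numeric samples of equal length.
#' @inheritParams mann_whitney
#' @return A [`comp_test`][new_comp_test] with `statistic = V` and field
#'   `n_zero` counting the dropped zero differences.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (anyNA(c(x, y))) abort("missing values are not supported")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("all paired differences are zero; p = 1")
    return(new_comp_test(NA_real_, 1, "Wilcoxon signed-rank test (degenerate)",
                         alternative, n_zero = n_zero, exact = FALSE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0L
  exact <- !has_ties && n <= 25L
  if (exact) {
    counts <- signedrank_counts(n)
    probs <- counts / 2^n
    vals <- seq_along(counts) - 1
    p_le <- sum(probs[vals <= v])
    p_ge <- sum(probs[vals >= v])
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two_sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact Wilcoxon signed-rank test"
  } else {
    mu <- n * (n + 1) / 4
    tie_table <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(tie_table^3 - tie_table) / 48)
    z <- v - mu
    cc <- switch(alternative, two_sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two_sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  new_comp_test(v, p, method, alternative,
                n = n, n_zero = n_zero, exact = exact)
}

#' Friedman rank-sum test
#'
#' Chi-square approximation for `k` related treatments observed over `b`
#' blocks, with midranks within blocks and the usual tie correction in the
#' denominator. A block whose entries are all equal simply contributes flat
#' midranks; if every block is flat the statistic is 0 and p = 1.
#'
#' @param block_matrix Numeric matrix, blocks in rows, treatments in columns
#'   (at least 2 of each).
#' @return A [`comp_test`][new_comp_test] with the chi-square statistic and
#'   `df = k - 1`.
#' @export
friedman_rank <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (!is.numeric(m) || anyNA(m)) abort("block_matrix must be numeric without NAs")
  b <- nrow(m); k <- ncol(m)
  if (b < 2L || k < 2L) abort("need >= 2 blocks and >= 2 treatments")
  r <- t(apply(m, 1L, rank))
  tie_term <- sum(apply(r, 1L, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  denom <- b * k * (k + 1) - tie_term / (k - 1)
  num <- 12 * sum((colSums(r) - b * (k + 1) / 2)^2)
  stat <- if (denom <= 0) 0 else num / denom
  p <- if (stat == 0 && denom <= 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  new_comp_test(stat, p, "Friedman rank-sum test",
                alternative = "two_sided", df = k - 1L, n_blocks = b)
}

#' Pearson correlation test
#'
#' Product-moment correlation with the t-distribution p-value on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @inheritParams mann_whitney
#' @return A [`comp_test`][new_comp_test] with `statistic = r` and fields
#'   `t` and `df`.
#' @export
pearson_cor <- function(x, y, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  r <- cor(x, y)
  df <- n - 2L
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- switch(alternative,
    two_sided = 2 * pt(-abs(tstat), df),
    greater = pt(tstat, df, lower.tail = FALSE),
    less = pt(tstat, df))
  new_comp_test(r, min(1, p), "Pearson correlation test", alternative,
                t = tstat, df = df, n = n)
}
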