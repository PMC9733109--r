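#' Construct a hypothesis-test result
#'
#' Light container used by every test in the statistics kernel. Permutation
#' tests record the number of permutations and the RNG seed so that any
#' reported p-value can be regenerated bit-exactly; exact and analytic tests
#' carry `n_perm = 0`.
#'
#' @param statistic Numeric test statistic.
#' @param p_value p-value in `[0, 1]`.
#' @param method Short human-readable label.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @param n_perm Number of permutations used (0 for exact/analytic tests).
#' @param seed RNG seed used for permutations (`NA` when deterministic).
#' @param ... Further named fields stored on the object (e.g. `n`, `df`).
#'
#' @return An object of class `comp_test`.
#' @keywords internal
new_comp_test <- function(statistic, p_value, method,
                          alternative = "two_sided", ...,
                          n_perm = 0L, seed = NA_integer_) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L)
  if (is.finite(p_value) && (p_value < 0 || p_value > 1)) {
    abort("p_value must lie in [0, 1]")
  }
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, alternative = alternative,
         n_perm = as.integer(n_perm), seed = seed, ...),
    class = "comp_test"
  )
}

#' @export
print.comp_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %.6g, p = %.4g (%s)\n",
              x$statistic, x$p_value, gsub("_", "-", x$alternative)))
  if (x$n_perm > 0L) {
    cat(sprintf("%d permutations, seed %s\n", x$n_perm, format(x$seed)))
  }
  invisible(x)
}

#' Tidy a `comp_test` result into a one-row tibble
#'
#' @param x A `comp_test` object.
#' @param ... Unused.
#' @return A tibble with columns `method`, `statistic`, `p.value`,
#'   `alternative`, `n_perm`, `seed`.
#' @export
tidy.comp_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    alternative = x$alternative,
    n_perm = x$n_perm,
    seed = as.integer(x$seed)
  )
}

#' @rdname tidy.comp_test
#' @export
glance.comp_test <- function(x, ...) tidy(x, ...)

#' Serialize a set of test results to a flat table
#'
#' @param tests A named list of `comp_test` objects.
#' @return A tibble with one row per test, the list names in column `test`.
#' @export
tidy_tests <- function(tests) {
  stopifnot(is.list(tests))
  dplyr::bind_rows(purrr::map(tests, tidy), .id = "test")
}

match_alternative <- function(alternative) {
  match.arg(alternative, c("two_sided", "greater", "less"))
}
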