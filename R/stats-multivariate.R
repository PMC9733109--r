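# Distance-based ordination and permutation tests. Permutation p-values
# throughout use the add-one estimator (1 + exceedances) / (n_perm + 1) and
# are reproducible from (seed, n_perm).

as_dist_matrix <- function(dm, arg = "dm") {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || !isSymmetric(unname(dm), tol = 1e-8)) {
    abort(sprintf("%s must be a symmetric square matrix or 'dist'", arg))
  }
  if (any(abs(diag(dm)) > 1e-12)) abort(sprintf("%s must have a zero diagonal", arg))
  if (any(dm < -1e-12)) abort(sprintf("%s must be nonnegative", arg))
  dm
}

#' Bray-Curtis dissimilarity on raw counts
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` computed on the raw count
#' rows, giving values in `[0, 1]`: 0 for identical rows, 1 for rows with
#' disjoint support.
#'
#' @param count_matrix Nonnegative numeric matrix, individuals in rows.
#'   All-zero rows are rejected.
#' @return A symmetric dissimilarity matrix with a zero diagonal, labelled
#'   by the row names of the input.
#' @export
bray_curtis <- function(count_matrix) {
  m <- as.matrix(count_matrix)
  if (any(m < 0) || anyNA(m)) abort("counts must be nonnegative and complete")
  if (any(rowSums(m) == 0)) abort("all-zero rows are not admissible")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  d
}

#' Principal component analysis of a behaviour count table
#'
#' Rare behaviour columns whose grand total falls at or below
#' `min_total_fraction` of all recorded events are dropped, rows are
#' converted to per-individual proportions, columns are centred, and the
#' covariance matrix is eigendecomposed. Component signs are fixed by making
#' the largest-magnitude loading of each component positive, so results are
#' reproducible across platforms.
#'
#' @param count_matrix Individuals x behaviours count matrix.
#' @param min_total_fraction Keep a behaviour only if it accounts for more
#'   than this fraction of all events (default 0.05).
#' @return An object of class `counts_pca`: list with `scores`, `loadings`,
#'   `var_explained` (sums to 1 over all components), `kept`, `dropped`.
#' @export
pca_counts <- function(count_matrix, min_total_fraction = 0.05) {
  m <- as.matrix(count_matrix)
  if (nrow(m) < 3L) abort("need at least 3 individuals")
  if (any(m < 0) || anyNA(m)) abort("counts must be nonnegative and complete")
  frac <- colSums(m) / sum(m)
  keep <- frac > min_total_fraction
  if (sum(keep) < 2L) abort("fewer than 2 behaviours survive the frequency filter")
  kept <- m[, keep, drop = FALSE]
  if (any(rowSums(kept) == 0)) abort("an individual has no events among retained behaviours")
  props <- sweep(kept, 1L, rowSums(kept), "/")
  centred <- scale(props, center = TRUE, scale = FALSE)
  eig <- eigen(cov(centred), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  loadings <- eig$vectors
  # deterministic sign convention
  for (j in seq_len(ncol(loadings))) {
    imax <- which.max(abs(loadings[, j]))
    if (loadings[imax, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- centred %*% loadings
  ve <- if (sum(vals) > 0) vals / sum(vals) else rep(0, length(vals))
  dimnames(loadings) <- list(colnames(kept), paste0("PC", seq_len(ncol(loadings))))
  colnames(scores) <- colnames(loadings)
  structure(
    list(scores = scores, loadings = loadings, var_explained = ve,
         kept = colnames(kept), dropped = colnames(m)[!keep]),
    class = "counts_pca"
  )
}

#' @export
print.counts_pca <- function(x, ...) {
  cat(sprintf("PCA of %d individuals x %d behaviours (dropped: %s)\n",
              nrow(x$scores), length(x$kept),
              if (length(x$dropped)) paste(x$dropped, collapse = ", ") else "none"))
  cat("variance explained:", paste0(sprintf("%.1f%%", 100 * head(x$var_explained, 4)),
                                    collapse = ", "), "...\n")
  invisible(x)
}

#' @rdname pca_counts
#' @param x A `counts_pca` object.
#' @param ... Unused.
#' @export
tidy.counts_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "individual_id")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between-group versus within-group
#' dissimilarities, `R = (mean between-rank - mean within-rank) / (M / 2)`
#' with `M = n(n-1)/2`, so `R` lies in `[-1, 1]` and perfectly separated
#' groups give `R = 1`. Significance by random relabelling of individuals.
#'
#' @param dm Dissimilarity matrix or `dist`.
#' @param groups Group label per individual; every group needs >= 2 members.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer RNG seed for the permutations (default 1234).
#' @return A [`comp_test`][new_comp_test] with `statistic = R`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = 1234) {
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) abort("groups must match the matrix dimension")
  if (nlevels(droplevels(groups)) < 2L) abort("need at least 2 groups")
  if (any(table(groups) < 2L)) abort("every group needs at least 2 members")
  ut <- upper.tri(dm)
  rv <- rank(dm[ut])
  M <- n * (n - 1) / 2
  ii <- row(dm)[ut]; jj <- col(dm)[ut]
  r_of <- function(g) {
    within <- g[ii] == g[jj]
    (mean(rv[!within]) - mean(rv[within])) / (M / 2)
  }
  r_obs <- r_of(groups)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(k) r_of(groups[sample.int(n)]) >= r_obs,
               logical(1)))
  })
  p <- (1 + exceed) / (n_perm + 1)
  new_comp_test(r_obs, p, "ANOSIM", alternative = "greater",
                n_perm = as.integer(n_perm), seed = seed, n = n)
}

#' Mantel test for association between two distance matrices
#'
#' Pearson correlation between the upper triangles, with significance from
#' simultaneous row/column permutations of the second matrix.
#'
#' @param dm1,dm2 Distance matrices over the same individuals in the same
#'   order.
#' @inheritParams anosim_test
#' @return A [`comp_test`][new_comp_test] with `statistic = r`.
#' @export
mantel_test <- function(dm1, dm2, n_perm = 9999, seed = 1234) {
  dm1 <- as_dist_matrix(dm1, "dm1"); dm2 <- as_dist_matrix(dm2, "dm2")
  if (nrow(dm1) != nrow(dm2)) abort("dm1 and dm2 must have the same size")
  l1 <- rownames(dm1); l2 <- rownames(dm2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    abort("dm1 and dm2 must be labelled identically and in the same order")
  }
  n <- nrow(dm1)
  ut <- upper.tri(dm1)
  v1 <- dm1[ut]
  r_obs <- cor(v1, dm2[ut])
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      cor(v1, dm2[idx, idx][ut]) >= r_obs
    }, logical(1)))
  })
  p <- (1 + exceed) / (n_perm + 1)
  new_comp_test(r_obs, p, "Mantel test", alternative = "greater",
                n_perm = as.integer(n_perm), seed = seed, n = n)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type-I) partitioning of the total squared distance among
#' individuals, in the style of the `adonis` family: the response is
#' log(x+1)-transformed and column-standardised (optional), Euclidean
#' distances are Gower-centred, and each term's sum of squares is the trace
#' of its incremental hat-matrix projection. Pseudo-F per term; p-values by
#' permutation of the raw rows.
#'
#' @param response Individuals x variables numeric table (no missing values).
#' @param predictors Data frame of factors/covariates, entered in the given
#'   column order.
#' @param transform If `TRUE` (default) apply log(x+1) and column
#'   standardisation before computing Euclidean distances.
#' @inheritParams anosim_test
#' @return A `permanova_fit`: tibble with one row per term plus residual and
#'   total rows (`term`, `df`, `sum_sq`, `r_squared`, `pseudo_f`, `p_value`).
#' @export
permanova_test <- function(response, predictors, n_perm = 999, seed = 1234,
                           transform = TRUE) {
  y <- as.matrix(response)
  if (anyNA(y)) abort("response must not contain missing values")
  pred <- as.data.frame(predictors)
  if (anyNA(pred)) abort("predictors must not contain missing values")
  n <- nrow(y)
  if (nrow(pred) != n) abort("response and predictors must have matching rows")
  if (transform) {
    if (any(y < 0)) abort("log(x+1) transform requires nonnegative response")
    y <- log1p(y)
    sds <- apply(y, 2L, sd)
    y <- scale(y, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  d2 <- as.matrix(stats::dist(y))^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  G <- ctr %*% (-d2 / 2) %*% ctr

  terms <- names(pred)
  X <- matrix(1, n, 1) # intercept
  hats <- list()
  dfs <- integer(0)
  kept_terms <- character(0)
  rank_prev <- 1L
  for (tm in terms) {
    mm <- stats::model.matrix(~value, data = data.frame(value = pred[[tm]]))[, -1, drop = FALSE]
    Xc <- cbind(X, mm)
    qr_c <- qr(Xc)
    df_t <- qr_c$rank - rank_prev
    if (df_t < 1L) {
      warn(sprintf("predictor '%s' is rank-deficient given earlier terms; dropped", tm))
      next
    }
    X <- Xc
    rank_prev <- qr_c$rank
    Q <- qr.Q(qr_c)[, seq_len(qr_c$rank), drop = FALSE]
    hats[[tm]] <- tcrossprod(Q)
    dfs <- c(dfs, df_t)
    kept_terms <- c(kept_terms, tm)
  }
  if (length(kept_terms) == 0L) abort("no usable predictor terms")
  n_terms <- length(kept_terms)
  H_full <- hats[[n_terms]]
  df_res <- n - rank_prev
  if (df_res < 1L) abort("model saturates the data; no residual degrees of freedom")

  # incremental projectors (intercept-only hat for the first term's baseline)
  H_prev <- matrix(1 / n, n, n)
  deltas <- vector("list", n_terms)
  for (k in seq_len(n_terms)) {
    deltas[[k]] <- hats[[k]] - H_prev
    H_prev <- hats[[k]]
  }
  ss_total <- sum(diag(G))
  f_of <- function(Gp) {
    ss <- vapply(deltas, function(Hd) sum(Hd * Gp), numeric(1))
    ss_res <- sum(diag(Gp)) - sum(H_full * Gp)
    list(ss = ss, ss_res = ss_res, f = (ss / dfs) / (ss_res / df_res))
  }
  obs <- f_of(G)
  exceed <- numeric(n_terms)
  withr::with_seed(seed, {
    for (k in seq_len(n_perm)) {
      idx <- sample.int(n)
      fp <- f_of(G[idx, idx])$f
      exceed <- exceed + (fp >= obs$f)
    }
  })
  pvals <- (1 + exceed) / (n_perm + 1)
  out <- tibble::tibble(
    term = c(kept_terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r_squared = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA)
  )
  structure(out, class = c("permanova_fit", class(out)),
            n_perm = as.integer(n_perm), seed = seed)
}

#' @rdname permanova_test
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname permanova_test
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(
    n = sum(x$df[x$term %in% c("Residual")] + 0) + sum(x$df[!x$term %in% c("Residual", "Total")]) + 1,
    n_terms = sum(!x$term %in% c("Residual", "Total")),
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed")
  )
}
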