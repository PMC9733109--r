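test_that("Bray-Curtis matches the hand formula and the reference", {
  m <- rbind(a = c(1, 2, 0, 4), b = c(1, 2, 0, 4), c = c(0, 0, 5, 0))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1) # disjoint support
  expect_equal(d["b", "c"], 1)
  m2 <- rbind(x = c(3, 0, 1, 2), y = c(1, 1, 1, 1), z = c(0, 4, 0, 0))
  d2 <- bray_curtis(m2)
  expect_equal(d2["x", "y"], (2 + 1 + 0 + 1) / (4 + 1 + 2 + 3))
  set.seed(81)
  cm <- matrix(rpois(60, 4), 10, 6)
  expect_equal(max(abs(bray_curtis(cm) - as.matrix(vegan::vegdist(cm)))), 0,
               tolerance = 1e-12)
  expect_error(bray_curtis(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_true(all(bray_curtis(cm) >= 0 & bray_curtis(cm) <= 1))
})

test_that("behaviour PCA has the spectral properties and matches prcomp", {
  set.seed(82)
  m <- matrix(rpois(80, 10), 8, 10)
  rownames(m) <- paste0("i", 1:8)
  res <- pca_counts(m, min_total_fraction = 0)
  # orthonormal loadings, nonincreasing variance summing to 1
  expect_equal(crossprod(res$loadings), diag(ncol(res$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(res$var_explained) <= 1e-12))
  expect_equal(sum(res$var_explained), 1, tolerance = 1e-8)
  # same subspace as prcomp on the identical proportion matrix
  props <- sweep(m, 1, rowSums(m), "/")
  ref <- prcomp(props, center = TRUE, scale. = FALSE)
  expect_equal(abs(cor(res$scores[, 1], ref$x[, 1])), 1, tolerance = 1e-8)
})

test_that("behaviour PCA separates constructed phenotypes on PC1", {
  set.seed(83)
  aggressive <- t(sapply(1:6, function(i) rmultinom(1, 60, c(5, 5, 1, 1))))
  timid <- t(sapply(1:6, function(i) rmultinom(1, 60, c(1, 1, 5, 5))))
  m <- rbind(aggressive, timid)
  colnames(m) <- c("attack", "chase", "flight", "vocalization")
  rownames(m) <- paste0("i", 1:12)
  res <- pca_counts(m, min_total_fraction = 0)
  g1 <- res$scores[1:6, 1]; g2 <- res$scores[7:12, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("behaviour PCA frequency filter and degenerate input behave", {
  m <- cbind(common1 = c(30, 30, 30), common2 = c(30, 30, 30),
             rare = c(1, 1, 2)) # rare = 4/184 < 5%
  res <- pca_counts(m, min_total_fraction = 0.05)
  expect_false("rare" %in% res$kept)
  expect_equal(res$dropped, "rare")
  # identical rows: no variance anywhere
  flat <- matrix(rep(c(5, 3, 2), each = 4), 4, 3)
  resf <- pca_counts(flat, min_total_fraction = 0)
  expect_true(all(resf$var_explained == 0))
  expect_error(pca_counts(m[, 1, drop = FALSE], 0.05), "fewer than 2")
  expect_error(pca_counts(m[1:2, ], 0), "3 individuals")
})

test_that("ANOSIM statistic matches vegan and R = 1 at perfect separation", {
  set.seed(84)
  pts <- rbind(matrix(rnorm(12, 0), 6, 2), matrix(rnorm(12, 10), 6, 2))
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 6)
  res <- anosim_test(d, g, n_perm = 99, seed = 3)
  expect_equal(res$statistic, 1)
  pts2 <- matrix(rnorm(24), 12, 2)
  d2 <- as.matrix(dist(pts2))
  res2 <- anosim_test(d2, g, n_perm = 199, seed = 3)
  ref <- vegan::anosim(as.dist(d2), g, permutations = 19)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_true(res2$statistic >= -1 && res2$statistic <= 1)
  expect_error(anosim_test(d2, c(rep("a", 11), "b")), "2 members")
})

test_that("ANOSIM permutation p converges to the exhaustive label enumeration", {
  set.seed(85)
  pts <- matrix(rnorm(12) + rep(c(0, 1.2), each = 3), 6, 2)
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  # exhaustive: all choose(6,3) distinct assignments of the 'a' set
  ut <- upper.tri(d); rv <- rank(d[ut]); M <- 15
  ii <- row(d)[ut]; jj <- col(d)[ut]
  r_of <- function(gg) {
    w <- gg[ii] == gg[jj]
    (mean(rv[!w]) - mean(rv[w])) / (M / 2)
  }
  r_obs <- r_of(g)
  sets <- combn(6, 3)
  rs <- apply(sets, 2, function(s) r_of(ifelse(seq_len(6) %in% s, "a", "b")))
  p_exact <- mean(rs >= r_obs - 1e-12)
  res <- anosim_test(d, g, n_perm = 1999, seed = 6)
  expect_equal(res$statistic, r_obs, tolerance = 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 0.035)
})

test_that("Mantel statistic matches vegan, is 1 on itself, exhaustive on 5 points", {
  set.seed(86)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  expect_equal(mantel_test(d1, d1, n_perm = 19, seed = 1)$statistic, 1)
  res <- mantel_test(d1, d2, n_perm = 99, seed = 2)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 19)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  # exhaustive enumeration over all 5! simultaneous permutations
  a <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  b <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  ut <- upper.tri(a)
  v1 <- a[ut]
  perms <- all_perms(5)
  rs <- apply(perms, 1, function(px) cor(v1, b[px, px][ut]))
  r_obs <- cor(v1, b[ut])
  p_exact <- mean(rs >= r_obs - 1e-12)
  resx <- mantel_test(a, b, n_perm = 4999, seed = 4)
  expect_equal(resx$p_value, p_exact, tolerance = 0.04)
  expect_error(mantel_test(d1, a), "same size")
})

test_that("PERMANOVA partition matches adonis2 term by term", {
  set.seed(87)
  n <- 18
  resp <- matrix(rexp(n * 4, 0.1), n, 4)
  pred <- data.frame(pop = factor(rep(c("A", "B"), each = n / 2)),
                     sex = factor(sample(c("M", "F"), n, TRUE)),
                     wt = rnorm(n, 20, 3))
  fit <- permanova_test(resp, pred, n_perm = 99, seed = 5)
  y <- scale(log1p(resp))
  ref <- vegan::adonis2(dist(y) ~ pop + sex + wt, data = pred,
                        permutations = 19, by = "terms")
  expect_equal(fit$sum_sq[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(fit$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(fit$df[1:4], ref$Df[1:4])
  expect_equal(sum(fit$sum_sq[1:4]), fit$sum_sq[5], tolerance = 1e-8)
})

test_that("PERMANOVA single-factor partition equals the direct group decomposition", {
  set.seed(88)
  n <- 12
  resp <- matrix(rnorm(n * 3, 10, 2), n, 3)
  g <- factor(rep(c("A", "B"), each = n / 2))
  fit <- permanova_test(resp, data.frame(g = g), n_perm = 49, seed = 1)
  # direct: SS_total - sum of within-group SS on the transformed coordinates
  y <- scale(log1p(resp))
  d <- as.matrix(dist(y))^2
  ss_tot <- sum(d[upper.tri(d)]) / n
  ss_within <- sum(sapply(levels(g), function(l) {
    dl <- d[g == l, g == l]
    sum(dl[upper.tri(dl)]) / sum(g == l)
  }))
  expect_equal(fit$sum_sq[fit$term == "g"], ss_tot - ss_within, tolerance = 1e-8)
  expect_equal(fit$sum_sq[fit$term == "Residual"], ss_within, tolerance = 1e-8)
})

test_that("PERMANOVA pseudo-F grows with separation and drops aliased terms", {
  set.seed(89)
  n <- 16
  g <- factor(rep(c("A", "B"), each = n / 2))
  f_at <- function(shift) {
    resp <- matrix(rnorm(n * 3), n, 3) + outer(as.numeric(g) - 1, rep(shift, 3))
    permanova_test(resp, data.frame(g = g), n_perm = 19, seed = 2,
                   transform = FALSE)$pseudo_f[1]
  }
  expect_lt(f_at(0.2), f_at(2))
  expect_lt(f_at(2), f_at(8))
  pred <- data.frame(g = g, g2 = g) # aliased copy
  expect_warning(fit <- permanova_test(matrix(rexp(n * 3), n, 3), pred,
                                       n_perm = 19, seed = 3),
                 "rank-deficient")
  expect_false("g2" %in% fit$term)
})

test_that("permutation tests are bit-reproducible from their seed", {
  set.seed(90)
  d1 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  g <- rep(c("a", "b"), each = 4)
  expect_identical(anosim_test(d1, g, 199, seed = 42)$p_value,
                   anosim_test(d1, g, 199, seed = 42)$p_value)
  expect_identical(mantel_test(d1, d2, 199, seed = 42)$p_value,
                   mantel_test(d1, d2, 199, seed = 42)$p_value)
  resp <- matrix(rnorm(24), 8, 3)
  expect_identical(
    permanova_test(resp, data.frame(g = g), 99, seed = 7, transform = FALSE)$p_value,
    permanova_test(resp, data.frame(g = g), 99, seed = 7, transform = FALSE)$p_value)
})
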