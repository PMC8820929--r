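# small deterministic table used by several tests
toy_table <- function() {
  data.frame(
    a = c(1, 2, 3, 4, 5),
    b = c(2.1, 3.9, 6.2, 7.8, 10.1),
    c = c(5, 3, 4, 1, 2))
}

test_that("correlation matrix matches a hand-computed Pearson formula", {
  tab <- toy_table()
  res <- trait_correlations(tab, "pearson")
  # direct formula on 5 rows
  r_hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(res$matrix["a", "b"], r_hand(tab$a, tab$b),
               tolerance = 1e-10)
  expect_equal(res$matrix["a", "c"], r_hand(tab$a, tab$c),
               tolerance = 1e-10)
  expect_true(all(diag(res$matrix) == 1))
  expect_true(isSymmetric(res$matrix))
  expect_true(all(abs(res$matrix) <= 1 + 1e-12))
})

test_that("correlation-range categories overlap as printed", {
  # two exactly linearly related columns land in category D
  tab <- data.frame(a = 1:6, b = 2 * (1:6) + 3, c = c(2, 1, 4, 3, 6, 5))
  res <- trait_correlations(tab)
  expect_true(all(c("a", "b") %in% res$categories$D))
  # the diagonal is never categorized: a variable with only weak
  # off-diagonal correlations must not reach D
  expect_false("c" %in% res$categories$D)
  # overlapping ranges: a correlation of exactly 0.05 lists the pair
  # in both A and B
  x <- 1:8
  y0 <- resid(lm(c(2, 7, 1, 8, 2, 8, 1, 9) ~ x))
  v <- as.vector(scale(x)); u <- as.vector(scale(y0))
  tab2 <- data.frame(x = x, y = 0.05 * v + sqrt(1 - 0.05^2) * u)
  res2 <- trait_correlations(tab2)
  r <- res2$matrix["x", "y"]
  expect_equal(r, 0.05, tolerance = 1e-10)
  expect_true(all(c("x", "y") %in% res2$categories$A))
  expect_true(all(c("x", "y") %in% res2$categories$B))
})

test_that("constant columns are flagged, not fatal", {
  tab <- cbind(toy_table(), flat = 7)
  res <- trait_correlations(tab)
  expect_identical(res$constant, "flat")
})

test_that("KMO is exactly 0.5 for any correlated 2-variable table", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(30); y <- 0.6 * x + rnorm(30)
    expect_equal(as.numeric(kmo(data.frame(a = x, b = y))), 0.5,
                 tolerance = 1e-12)
  }
})

test_that("KMO shrinks toward 0 as correlations vanish", {
  set.seed(10)
  tab <- as.data.frame(matrix(rnorm(5000), 1000, 5))
  expect_lt(as.numeric(kmo(tab)), 0.6)
  # and KMO is always inside [0, 1]
  tabc <- as.data.frame(MASS::mvrnorm(200, rep(0, 4),
                                      0.7 + 0.3 * diag(4)))
  k <- as.numeric(kmo(tabc))
  expect_gte(k, 0); expect_lte(k, 1)
})

test_that("KMO agrees with regress-out partial correlations", {
  # independent oracle: anti-image partials computed by residualizing
  # each pair on all remaining variables with lm()
  set.seed(77)
  n <- 120
  z <- rnorm(n)
  tab <- data.frame(a = z + rnorm(n, sd = 0.8),
                    b = z + rnorm(n, sd = 0.8),
                    c = rnorm(n),
                    d = -z + rnorm(n, sd = 0.9))
  X <- scale(as.matrix(tab))
  p <- ncol(X)
  U <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    if (i == j) next
    others <- X[, -c(i, j), drop = FALSE]
    ri <- resid(lm(X[, i] ~ others))
    rj <- resid(lm(X[, j] ~ others))
    U[i, j] <- cor(ri, rj)
  }
  R <- cor(X); diag(R) <- 0
  kmo_oracle <- sum(R^2) / (sum(R^2) + sum(U^2))
  expect_equal(as.numeric(kmo(tab)), kmo_oracle, tolerance = 1e-6)
})

test_that("Bartlett sphericity: identity, near-singular, and formula", {
  # exact identity correlation: chi2 = 0, p = 1
  tab0 <- data.frame(u = rep(c(1, 1, -1, -1), 10),
                     v = rep(c(1, -1, 1, -1), 10))
  stopifnot(cor(tab0$u, tab0$v) == 0)
  bt0 <- bartlett_sphericity(tab0)
  expect_equal(bt0$chi2, 0, tolerance = 1e-10)
  expect_equal(bt0$p_value, 1, tolerance = 1e-10)

  # (near-)perfectly correlated pair: determinant collapses, so either
  # the positive-definite guard fires or chi2 explodes
  dup <- data.frame(a = rnorm(20))
  dup$b <- 2 * dup$a
  res <- tryCatch(bartlett_sphericity(dup), error = identity)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "positive definite")
  } else {
    expect_gt(res$chi2, 100)
  }

  # 5-variable table vs the formula evaluated through eigenvalues
  set.seed(5)
  tab <- as.data.frame(MASS::mvrnorm(60, rep(0, 5),
                                     0.4 + 0.6 * diag(5)))
  bt <- bartlett_sphericity(tab)
  R <- cor(tab)
  ln_det <- sum(log(eigen(R, symmetric = TRUE,
                          only.values = TRUE)$values))
  chi2_hand <- -(60 - 1 - (2 * 5 + 5) / 6) * ln_det
  expect_equal(bt$chi2, chi2_hand, tolerance = 1e-8)
  expect_equal(bt$df, 10)
  expect_equal(bt$p_value, pchisq(chi2_hand, 10, lower.tail = FALSE))
})

test_that("agglomeration schedule reproduces hand-worked 1-D merges", {
  # three variables at 0, 1, 10 (one instance each coordinate):
  # squared distances 1, 81, 100
  tab <- data.frame(p0 = 0, p1 = 1, p2 = 10)
  fit <- trait_agglomerate(tab, "nearest", k = 2, scale. = FALSE)
  expect_equal(fit$schedule$coefficient, c(1, 81))
  expect_equal(fit$schedule$cluster1, c(1, 1))
  expect_equal(fit$schedule$cluster2, c(2, 3))
  expect_equal(fit$schedule$first_appears1, c(0, 1))
  expect_equal(unname(fit$membership), c(1, 1, 2))

  # two identical variables merge first at coefficient 0
  tab2 <- data.frame(a = c(1, 5, 3), b = c(1, 5, 3), c = c(9, 2, 7))
  fit2 <- trait_agglomerate(tab2, "nearest", k = 2, scale. = FALSE)
  expect_equal(fit2$schedule$coefficient[1], 0)
  expect_equal(unname(fit2$membership), c(1, 1, 2))
})

test_that("single-linkage schedule coefficients never decrease", {
  tab <- make_feature_table(100, seed = 9)
  fit <- trait_agglomerate(tab, "nearest", k = 3)
  expect_equal(nrow(fit$schedule), 22)   # n_variables - 1 stages
  expect_true(all(diff(fit$schedule$coefficient) >= -1e-9))
  expect_true(all(fit$schedule$first_appears1 < fit$schedule$stage))
  expect_true(all(fit$schedule$first_appears2 < fit$schedule$stage))
})

test_that("planted three-block structure is recovered by all linkages", {
  tab <- make_feature_table(200, within_r = 0.9, between_r = 0,
                            seed = 4)
  cmp <- compare_linkages(tab, k = 3)
  expect_identical(nrow(cmp), 23L)
  # all seven linkage columns agree exactly
  for (l in linkage_methods[-1]) {
    expect_identical(cmp[[l]], cmp[["between"]])
  }
  # and the clusters are the planted blocks
  planted <- rep(NA_integer_, 23)
  names(planted) <- cmp$variable
  for (b in seq_along(default_trait_blocks)) {
    planted[default_trait_blocks[[b]]] <- b
  }
  # canonicalized ids: map planted labels by first appearance too
  planted <- match(planted, unique(planted))
  expect_identical(cmp[["nearest"]], planted)
})

test_that("membership is invariant to instance-row permutation", {
  tab <- make_feature_table(150, seed = 12)
  cmp1 <- compare_linkages(tab, k = 3)
  set.seed(1)
  cmp2 <- compare_linkages(tab[sample(nrow(tab)), ], k = 3)
  expect_identical(cmp1, cmp2)
})

test_that("k = 1 collapses every variable into one cluster", {
  tab <- make_feature_table(50, seed = 3)
  cmp <- compare_linkages(tab, k = 1)
  for (l in linkage_methods) expect_true(all(cmp[[l]] == 1L))
})

test_that("clustering input validation", {
  expect_error(trait_agglomerate(data.frame(a = 1:5, b = 2:6), k = 3),
               "fewer variables")
})
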