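test_that("rank-1 data put all variance on axis 1", {
  withr::with_seed(1, {
    a <- rnorm(15)
    y <- cbind(a = a, b = 2 * a, c = -0.5 * a)
  })
  fit <- fit_pca(y)
  expect_equal(fit$prop_axes[1], 1, tolerance = 1e-10)
  expect_equal(length(fit$eigenvalues), 1)
})

test_that("PCA eigenvalues match the covariance eigendecomposition oracle", {
  y <- as.matrix(random_counts(20, 4, seed = 5))
  fit <- fit_pca(y)
  want <- eigen(stats::cov(y), symmetric = TRUE)$values
  expect_equal(fit$eigenvalues, want[want > 1e-12 * want[1]],
               tolerance = 1e-10)
  expect_equal(sum(fit$prop_axes), 1, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
})

test_that("PCA agrees with the vegan reference on transformed data", {
  y <- hellinger_transform(random_counts(25, 3, seed = 6))
  fit <- fit_pca(y)
  vfit <- vegan::rda(as.matrix(y))
  expect_equal(unname(fit$eigenvalues),
               unname(vfit$CA$eig)[seq_along(fit$eigenvalues)],
               tolerance = 1e-10)
})

test_that("RDA fitted values and R2 match the explicit hat-matrix oracle", {
  withr::with_seed(9, {
    Y <- matrix(rnorm(12), 6, 2)
    X <- matrix(rnorm(6), 6, 1)
  })
  fit <- fit_rda(Y, X)
  oracle <- hat_rda_oracle(Y, X)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
  # reconstruct fitted values from the ordination pieces
  recon <- fit$scores %*% t(fit$loadings)
  expect_lt(max(abs(recon - oracle$fitted)), 1e-8)
})

test_that("RDA R2 and constrained eigenvalues agree with vegan", {
  y <- hellinger_transform(random_counts(30, 4, seed = 13))
  x <- as.data.frame(matrix(rnorm(30 * 3), 30,
                            dimnames = list(NULL, c("u", "v", "w"))))
  fit <- fit_rda(y, x)
  vfit <- vegan::rda(as.matrix(y) ~ u + v + w, data = x)
  expect_equal(fit$r2, unname(vegan::RsquareAdj(vfit)$r.squared),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, unname(vegan::RsquareAdj(vfit)$adj.r.squared),
               tolerance = 1e-10)
  expect_equal(unname(fit$eigenvalues),
               unname(vfit$CCA$eig)[seq_along(fit$eigenvalues)],
               tolerance = 1e-10)
})

test_that("a perfectly explanatory X gives R2 = 1 and zero residuals", {
  y <- as.matrix(random_counts(12, 2, seed = 17))
  fit <- fit_rda(y, y)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  R <- as.matrix(partial_residuals(y, y))
  expect_lt(max(abs(R)), 1e-8)
  pra <- fit_pra(y, y)
  expect_equal(length(pra$eigenvalues), 0)
})

test_that("rank-deficient X is rejected with the collinear column named", {
  y <- as.matrix(random_counts(10, 2, seed = 19))
  x <- data.frame(a = rnorm(10))
  x$b <- 2 * x$a
  expect_error(fit_rda(y, x), "collinear.*b")
  expect_error(fit_rda(y, matrix(rnorm(100), 10, 10)), "n > m \\+ 1")
})

test_that("partial residuals are orthogonal to X and SS decomposes exactly", {
  withr::with_seed(23, {
    Y <- matrix(rnorm(40), 20, 2)
    X <- matrix(rnorm(60), 20, 3)
  })
  R <- as.matrix(partial_residuals(Y, X))
  Xc <- scale(X, scale = FALSE)
  expect_lt(max(abs(crossprod(Xc, R))), 1e-8)
  Yc <- scale(Y, scale = FALSE)
  fit <- fit_rda(Y, X)
  ss_fit <- fit$r2 * sum(Yc^2)
  expect_equal(sum(Yc^2), ss_fit + sum(R^2), tolerance = 1e-8)
})

test_that("PRA equals PCA when X is orthogonal to Y, up to axis signs", {
  withr::with_seed(29, {
    Y0 <- matrix(rnorm(60), 30, 2)
    Yc <- scale(Y0, scale = FALSE)
    X0 <- matrix(rnorm(30), 30, 1)
  })
  # build X exactly orthogonal to the centred community columns
  X <- X0 - Yc %*% solve(crossprod(Yc)) %*% crossprod(Yc, X0)
  pra <- fit_pra(Yc, X)
  pca <- fit_pca(Yc)
  expect_equal(pra$eigenvalues, pca$eigenvalues, tolerance = 1e-8)
  for (j in seq_along(pca$eigenvalues)) {
    expect_equal(abs(pra$scores[, j]), abs(pca$scores[, j]), tolerance = 1e-6)
  }
  # inertia identity: PRA total = (1 - R2) x PCA total
  r2 <- fit_rda(Yc, X)$r2
  expect_equal(pra$total_inertia, (1 - r2) * pca$total_inertia,
               tolerance = 1e-10)
})

test_that("Ezekiel adjustment reproduces printed and algebraic endpoints", {
  expect_equal(round(adjusted_r2(0.46, 329, 10), 2), 0.44)
  expect_equal(adjusted_r2(0.46, 329, 10), 1 - 0.54 * 328 / 318,
               tolerance = 1e-12)
  expect_equal(adjusted_r2(1, 50, 5), 1)
  expect_equal(adjusted_r2(0, 11, 1), -1 / 9, tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 5, 4), "n > m \\+ 1")
  expect_error(adjusted_r2(1.2, 50, 5), "\\[0, 1\\]")
})

test_that("noise-only RDA has adjusted R2 centred on zero", {
  r2a <- vapply(seq_len(200), function(i) {
    withr::with_seed(1000 + i, {
      y <- matrix(rnorm(60), 30, 2)
      x <- matrix(rnorm(30), 30, 1)
    })
    fit_rda(y, x)$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(r2a)), 0.02)
})

test_that("RDA permutation test is exact for self-explanation and reproducible", {
  y <- as.matrix(random_counts(15, 2, seed = 37))
  t1 <- rda_perm_test(y, y, nperm = 99, seed = 3)
  expect_equal(t1$p_value, 1 / 100)
  t2 <- rda_perm_test(y, y, nperm = 99, seed = 3)
  expect_identical(t1, t2)
})

test_that("RDA permutation test is calibrated under the null", {
  rejections <- vapply(seq_len(200), function(i) {
    withr::with_seed(2000 + i, {
      y <- matrix(rnorm(40 * 2), 40, 2)
      x <- matrix(rnorm(40), 40, 1)
    })
    rda_perm_test(y, x, nperm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
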