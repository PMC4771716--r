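test_that("a strong true predictor is selected first, ahead of noise", {
  first_is_signal <- 0L
  noise_first <- 0L
  n_runs <- 30L
  for (i in seq_len(n_runs)) {
    withr::with_seed(3000 + i, {
      x_true <- rnorm(40)
      y <- cbind(x_true + rnorm(40, sd = 0.4), -x_true + rnorm(40, sd = 0.4))
      X <- data.frame(signal = x_true, noise = rnorm(40))
    })
    # gain ordering alone (adjusted-R2 cap off): signal must come first
    fs <- forward_select(y, X, nperm = 99, seed = i, global_adj_r2 = Inf)
    if (length(fs$selected) > 0 && fs$selected[1] == "signal") {
      first_is_signal <- first_is_signal + 1L
    }
    # full double-stopping rule: noise must never be admitted before signal
    fs2 <- forward_select(y, X, nperm = 99, seed = i)
    if (length(fs2$selected) > 0 && fs2$selected[1] == "noise") {
      noise_first <- noise_first + 1L
    }
  }
  expect_gte(first_is_signal, ceiling(0.95 * n_runs))
  expect_equal(noise_first, 0L)
})

test_that("pure-noise candidates yield an empty selection in most runs", {
  empty <- vapply(seq_len(60), function(i) {
    withr::with_seed(4000 + i, {
      y <- matrix(rnorm(40 * 2), 40, 2)
      X <- matrix(rnorm(40 * 3), 40, 3)
    })
    length(forward_select(y, X, nperm = 99, seed = i)$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("selection path matches the exhaustive greedy oracle", {
  for (seed in c(11, 12, 13)) {
    withr::with_seed(seed, {
      x1 <- rnorm(25); x2 <- rnorm(25); x3 <- rnorm(25)
      y <- cbind(2 * x1 + x2 + rnorm(25, sd = 0.3),
                 x2 - x3 + rnorm(25, sd = 0.3))
      X <- data.frame(x1 = x1, x2 = x2, x3 = x3)
    })
    # alpha near 1 and no adjusted-R2 cap: the full greedy path is followed
    fs <- forward_select(y, X, alpha = 0.99, nperm = 99, seed = seed,
                         global_adj_r2 = Inf)
    want <- greedy_forward_oracle(y, X)
    expect_equal(fs$selected, want[seq_along(fs$selected)])
    expect_equal(fs$steps$variable, fs$selected)
  }
})

test_that("selection respects the two stopping rules and is reproducible", {
  withr::with_seed(99, {
    x1 <- rnorm(40)
    y <- cbind(x1 + rnorm(40, sd = 0.5), rnorm(40))
    X <- data.frame(x1 = x1, n1 = rnorm(40), n2 = rnorm(40))
  })
  fs <- forward_select(y, X, nperm = 199, seed = 8)
  expect_true(all(fs$steps$p_value <= fs$alpha))
  expect_true(all(diff(c(0, fs$steps$r2_cum)) >= 0))
  if (nrow(fs$steps) > 0) {
    expect_true(all(fs$steps$adj_r2_cum <= fs$global_adj_r2 + 1e-8))
  }
  fs2 <- forward_select(y, X, nperm = 199, seed = 8)
  expect_identical(fs, fs2)
  expect_error(forward_select(y, X, alpha = 1.2), "between 0 and 1")
  expect_error(forward_select(y, X, nperm = 9), "at least 99")
})

test_that("semipartial R2 matches the nested-model difference oracle", {
  withr::with_seed(123, {
    y <- matrix(rnorm(30 * 2), 30, 2)
    X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
    Z <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("c", "d")))
  })
  got <- partial_rda_r2(y, X, Z)
  r2_xz <- fit_rda(y, cbind(X, Z))$r2
  r2_z <- fit_rda(y, Z)$r2
  expect_equal(got$r2, r2_xz - r2_z, tolerance = 1e-10)
  expect_equal(got$adj_r2,
               adjusted_r2(r2_xz, 30, 4) - adjusted_r2(r2_z, 30, 2),
               tolerance = 1e-10)
  # no conditioning set: plain RDA
  expect_equal(partial_rda_r2(y, X)$r2, fit_rda(y, X)$r2, tolerance = 1e-12)
  # X inside span(Z): nothing left to explain
  expect_equal(partial_rda_r2(y, Z[, 1, drop = FALSE] * 2, Z)$r2, 0,
               tolerance = 1e-10)
})

test_that("two-set partition fractions are additive and match vegan", {
  withr::with_seed(222, {
    y <- as.matrix(random_counts(40, 3, seed = 223))
    A <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a1", "a2")))
    B <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("b1", "b2")))
  })
  vp <- variation_partition(y, list(A = A, B = B), nperm = 99, seed = 1)
  fr <- vp$fractions
  expect_equal(sum(fr$adj_r2), 1, tolerance = 1e-10)
  vref <- vegan::varpart(y, A, B)$part$indfract$Adj.R.squared
  expect_equal(fr$adj_r2, vref, tolerance = 1e-8)
  expect_true(all(!is.na(fr$p_value[fr$testable])))
  expect_true(all(is.na(fr$p_value[!fr$testable])))
})

test_that("three-set partition is additive and matches vegan", {
  withr::with_seed(333, {
    y <- as.matrix(random_counts(45, 3, seed = 334))
    A <- matrix(rnorm(45 * 2), 45, 2)
    B <- matrix(rnorm(45 * 2), 45, 2)
    C <- matrix(rnorm(45), 45, 1)
  })
  vp <- variation_partition(y, list(A = A, B = B, C = C), nperm = 99, seed = 2)
  fr <- vp$fractions
  expect_equal(sum(fr$adj_r2), 1, tolerance = 1e-10)
  vref <- vegan::varpart(y, A, B, C)$part$indfract$Adj.R.square
  # vegan order: [a] [b] [c] [d]=ab [e]=bc [f]=ac [g] [h]=resid
  expect_equal(fr$adj_r2, vref, tolerance = 1e-8)
})

test_that("identical subsets share everything; orthogonal subsets share nothing", {
  withr::with_seed(444, {
    y <- as.matrix(random_counts(40, 3, seed = 445))
    A <- matrix(rnorm(40 * 2), 40, 2)
  })
  vp_same <- variation_partition(y, list(A = A, B = A + 0), nperm = 99,
                                 seed = 3)
  fr <- vp_same$fractions
  expect_lt(max(abs(fr$adj_r2[fr$testable])), 1e-8)
  expect_equal(fr$adj_r2[fr$fraction == "shared:A&B"],
               fit_rda(y, A)$adj_r2, tolerance = 1e-8)

  # sample-orthogonal predictor blocks: shared fraction collapses
  withr::with_seed(446, {
    Z <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 4), 100, 4))))[, 2:5]
  })
  A2 <- Z[, 1:2]
  B2 <- Z[, 3:4]
  y2 <- 3 * A2[, 1] + 2 * B2[, 1] + matrix(rnorm(100 * 2, sd = 0.5), 100, 2)
  vp_orth <- variation_partition(y2, list(A = A2, B = B2), nperm = 99,
                                 seed = 4)
  shared <- vp_orth$fractions$adj_r2[vp_orth$fractions$fraction == "shared:A&B"]
  expect_lt(abs(shared), 0.01)
})

test_that("partition fractions are invariant to subset order", {
  withr::with_seed(555, {
    y <- as.matrix(random_counts(35, 3, seed = 556))
    A <- matrix(rnorm(35 * 2), 35, 2)
    B <- matrix(rnorm(35), 35, 1)
  })
  vp1 <- variation_partition(y, list(A = A, B = B), nperm = 99, seed = 5)
  vp2 <- variation_partition(y, list(B = B, A = A), nperm = 99, seed = 5)
  expect_equal(vp1$fractions$adj_r2[vp1$fractions$fraction == "unique:A"],
               vp2$fractions$adj_r2[vp2$fractions$fraction == "unique:A"],
               tolerance = 1e-10)
  expect_equal(vp1$fractions$adj_r2[vp1$fractions$fraction == "residual"],
               vp2$fractions$adj_r2[vp2$fractions$fraction == "residual"],
               tolerance = 1e-10)
})

test_that("partition input validation rejects bad subset lists", {
  y <- as.matrix(random_counts(20, 2, seed = 661))
  A <- matrix(rnorm(20), 20, 1)
  expect_error(variation_partition(y, list(A = A)), "2 or 3")
  expect_error(variation_partition(y, list(A, A, A, A)), "2 or 3")
})
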