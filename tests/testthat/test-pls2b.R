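test_that("preprocessing centers, scales, and flags constant columns", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), d = c(0, 3, 9))
  pc <- pls_preprocess(x, "center")
  expect_equal(pc$x[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(pc$x), c(a = 0, b = 0, d = 0))

  ps <- pls_preprocess(x, "center_scale")
  expect_equal(ps$x[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(stats::sd(ps$x[, "a"]), 1)
  expect_equal(stats::sd(ps$x[, "d"]), 1)
  # constant column: all zeros plus a flag, not NaN
  expect_equal(ps$x[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(ps$constant), c(FALSE, TRUE, FALSE))
  expect_error(pls_preprocess(x[1:2, ], "center"), "at least 3")
  expect_error(pls_preprocess(cbind(c(1, NA, 3)), "center"), "missing")
})

test_that("identical single-column blocks give one perfect structure", {
  set.seed(2)
  z <- matrix(scale(rnorm(20)), ncol = 1)
  fit <- pls2b(z, z, mode = "center")
  expect_length(fit$singular_values, 1)
  expect_equal(abs(as.numeric(fit$weights_b1)), 1)
  expect_equal(cor(fit$scores_b1[, 1], fit$scores_b2[, 1]), 1)
  expect_equal(fit$variance_share, 1)
})

test_that("first singular value matches the brute-force grid oracle", {
  set.seed(14)
  for (i in 1:5) {
    p1 <- sample(1:3, 1); p2 <- sample(1:3, 1)
    b1 <- matrix(rnorm(8 * p1), 8, p1)
    b2 <- matrix(rnorm(8 * p2), 8, p2)
    fit <- pls2b(b1, b2, mode = "center")
    x1 <- sweep(b1, 2, colMeans(b1)); x2 <- sweep(b2, 2, colMeans(b2))
    oracle <- grid_max_cov(x1, x2, step_deg = 1)
    expect_equal(fit$singular_values[1] / (nrow(b1) - 1), oracle,
                 tolerance = 1e-3)
  }
})

test_that("latent-structure count equals the smaller block width", {
  sim <- generate_blocks(n = 40, p1 = 13, p2 = 26, seed = 5)
  fit <- pls2b(sim$b1, sim$b2)
  expect_length(fit$singular_values, 13)
  expect_equal(dim(fit$weights_b1), c(13, 13))
  expect_equal(dim(fit$weights_b2), c(26, 13))
  sim2 <- generate_blocks(n = 40, p1 = 4, p2 = 3, seed = 5)
  expect_length(pls2b(sim2$b1, sim2$b2)$singular_values, 3)
})

test_that("variance shares are squared singular values normalised to one", {
  expect_equal(variance_shares(c(2, 1, 1)), c(4, 1, 1) / 6)
  expect_equal(variance_shares(1.7), 1)
  expect_error(variance_shares(c(0, 0)), "undefined")
})

test_that("correlation loadings equal direct per-column Pearson correlations", {
  set.seed(33)
  b1 <- matrix(rnorm(20 * 4), 20, 4)
  b2 <- matrix(rnorm(20 * 5), 20, 5)
  fit <- pls2b(b1, b2)
  cl <- correlation_loadings(fit, b1, b2)
  # independent oracle: plain column-by-column cor()
  for (j in 1:4) for (k in seq_along(fit$singular_values)) {
    expect_equal(cl$corr_loadings_b1[j, k],
                 cor(b1[, j], fit$scores_b1[, k]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(abs(cl$corr_loadings_b1) <= 1 + 1e-12))
  expect_identical(cl$corr_loadings_b1, fit$corr_loadings_b1)
})

test_that("a variable identical or orthogonal to its score loads 1 or 0", {
  set.seed(8)
  z <- rnorm(30)
  fit <- pls2b(cbind(z), cbind(z), mode = "center")
  expect_equal(as.numeric(fit$corr_loadings_b1[1, 1]), 1)
  # construct a column orthogonal to the score
  s <- fit$scores_b1[, 1]
  y <- rnorm(30)
  y <- y - s * sum(y * (s - mean(s))) / sum(s * (s - mean(s)))
  expect_lt(abs(cor(y, s)), 1e-10)
  cl <- correlation_loadings(fit, cbind(z, y), cbind(z))
  expect_lt(abs(cl$corr_loadings_b1[2, 1]), 1e-10)
})

test_that("constant variables get zero loading and a flag", {
  set.seed(12)
  b1 <- cbind(rnorm(15), rep(2, 15))
  b2 <- matrix(rnorm(15 * 3), 15, 3)
  fit <- pls2b(b1, b2)
  expect_equal(fit$corr_loadings_b1[2, ],
               rep(0, length(fit$singular_values)), ignore_attr = TRUE)
  expect_equal(unname(fit$constant_b1), c(FALSE, TRUE))
})

test_that("significance mask follows the t-test and flips at the critical r", {
  n <- 162; alpha <- 0.05
  expect_false(significance_mask(0, n, alpha))
  expect_true(significance_mask(1, n, alpha))
  expect_true(significance_mask(-1, n, alpha))
  # invert the t CDF numerically, independently of the closed form
  r_crit <- uniroot(function(r) {
    2 * stats::pt(r * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                  lower.tail = FALSE) - alpha
  }, c(1e-6, 1 - 1e-6), tol = 1e-14)$root
  expect_equal(critical_r(n, alpha), r_crit, tolerance = 1e-10)
  eps <- 1e-8
  expect_false(significance_mask(r_crit - eps, n, alpha))
  expect_true(significance_mask(r_crit + eps, n, alpha))
  expect_true(significance_mask(-(r_crit + eps), n, alpha))
  # monotone in alpha: stricter alpha can only shrink the significant set
  set.seed(20)
  r <- matrix(runif(40, -1, 1), 8, 5)
  m05 <- significance_mask(r, n, 0.05)
  m01 <- significance_mask(r, n, 0.01)
  expect_true(all(m05 | !m01))
})

test_that("every fit satisfies the conservation invariants", {
  set.seed(40)
  cases <- list(
    generate_blocks(n = 30, p1 = 5, p2 = 9, snr = 2, seed = 41),
    generate_blocks(n = 15, p1 = 8, p2 = 4, snr = 0, seed = 42),
    generate_blocks(n = 50, p1 = 13, p2 = 26, snr = 1, seed = 43))
  for (cs in cases) {
    for (mode in c("center_scale", "center")) {
      fit <- pls2b(cs$b1, cs$b2, mode = mode)
      k <- length(fit$singular_values)
      expect_equal(crossprod(fit$weights_b1), diag(k), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(crossprod(fit$weights_b2), diag(k), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(sum(fit$variance_share), 1, tolerance = 1e-10)
      expect_true(all(diff(fit$singular_values) <= 1e-12))
      # score-pair cross-covariance is diagonal with d_k on the diagonal
      cc <- crossprod(fit$scores_b1, fit$scores_b2)
      expect_equal(cc, diag(fit$singular_values, k), tolerance = 1e-8,
                   ignore_attr = TRUE)
      # recorded convention: cov(t1_k, t2_k) = d_k / (n - 1)
      n <- fit$n_objects
      expect_equal(cov(fit$scores_b1[, 1], fit$scores_b2[, 1]),
                   fit$singular_values[1] / (n - 1), tolerance = 1e-10)
    }
  }
})

test_that("the sign convention makes refits deterministic", {
  sim <- generate_blocks(n = 25, p1 = 6, p2 = 7, seed = 50)
  f1 <- pls2b(sim$b1, sim$b2)
  f2 <- pls2b(sim$b1, sim$b2)
  expect_identical(f1$weights_b1, f2$weights_b1)
  for (j in seq_along(f1$singular_values)) {
    expect_gt(f1$weights_b1[which.max(abs(f1$weights_b1[, j])), j], 0)
  }
})

test_that("an orthogonal rotation of a centered block only rotates the weights", {
  set.seed(60)
  sim <- generate_blocks(n = 30, p1 = 5, p2 = 6, seed = 61)
  x1 <- pls_preprocess(sim$b1, "center")$x
  x2 <- pls_preprocess(sim$b2, "center")$x
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  f0 <- pls2b(x1, x2, mode = "center")
  fr <- pls2b(x1 %*% q, x2, mode = "center")
  expect_equal(fr$singular_values, f0$singular_values, tolerance = 1e-10)
  # weights rotate contravariantly, up to the per-column sign convention
  w_expect <- t(q) %*% f0$weights_b1
  for (j in seq_along(f0$singular_values)) {
    expect_equal(abs(sum(fr$weights_b1[, j] * w_expect[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("fits tolerate more variables than objects and exact collinearity", {
  set.seed(70)
  n <- 10
  b1 <- matrix(rnorm(n * 20), n, 20)
  b2 <- matrix(rnorm(n * 30), n, 30)
  b2[, 30] <- b2[, 1] + b2[, 2]   # exact linear combination
  b2[, 29] <- 2 * b2[, 3]
  fit <- pls2b(b1, b2)
  k <- length(fit$singular_values)
  expect_equal(k, 20)
  expect_equal(crossprod(fit$weights_b1), diag(k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(fit$variance_share), 1, tolerance = 1e-10)
})

test_that("planted weight vectors are recovered at high signal-to-noise", {
  # generate_blocks columns share a unit noise scale, so fit without the
  # per-column rescaling that would distort the planted direction
  sim <- generate_blocks(n = 162, p1 = 13, p2 = 26, snr = 50, seed = 80)
  fit <- pls2b(sim$b1, sim$b2, mode = "center")
  expect_gt(abs(cor(fit$weights_b1[, 1], sim$truth$u)), 0.999)
  expect_gt(abs(cor(fit$weights_b2[, 1], sim$truth$v)), 0.999)
})

test_that("input contracts are enforced", {
  sim <- generate_blocks(n = 12, p1 = 3, p2 = 4, seed = 90)
  expect_error(pls2b(sim$b1[1:2, ], sim$b2[1:2, ]), "at least 3")
  b1 <- sim$b1; b1[3, 2] <- NA
  expect_error(pls2b(b1, sim$b2), "missing")
  expect_error(pls2b(sim$b1, sim$b2[1:10, ]), "different numbers")
})

test_that("the permutation null is seeded and covers the observed share under the null", {
  sim <- generate_blocks(n = 60, p1 = 5, p2 = 8, snr = 0, seed = 100)
  f1 <- pls2b(sim$b1, sim$b2, n_perm = 99, seed = 7)
  f2 <- pls2b(sim$b1, sim$b2, n_perm = 99, seed = 7)
  expect_identical(f1$perm$null_share, f2$perm$null_share)
  expect_gt(f1$perm$p_value, 0.01)  # pure noise: share 1 not extreme
  sim2 <- generate_blocks(n = 60, p1 = 5, p2 = 8, snr = 4, seed = 101)
  expect_lt(pls2b(sim2$b1, sim2$b2, n_perm = 99, seed = 7)$perm$p_value, 0.05)
})
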