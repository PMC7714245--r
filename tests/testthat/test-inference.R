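test_that("LOOCV reproduces truth when the model class contains it", {
  X <- withr::with_seed(1, matrix(rnorm(60), 20, 3))
  y <- 2 + X %*% c(1, -2, 0.5)
  expect_equal(loocv_predict(X, y), as.numeric(y), tolerance = 1e-8)
})

test_that("intercept-only LOOCV predicts the leave-one-out mean", {
  y <- c(4, 8, 15, 16, 23, 42)
  pred <- loocv_predict(matrix(nrow = 6, ncol = 0), y)
  expect_equal(pred, vapply(1:6, function(i) mean(y[-i]), numeric(1)))
})

test_that("LOOCV via the hat identity equals explicit refitting", {
  X <- withr::with_seed(2, matrix(rnorm(80), 20, 4))
  y <- withr::with_seed(3, rnorm(20))
  pred <- loocv_predict(X, y)
  refit <- vapply(1:20, function(i) {
    fit <- lm(y[-i] ~ X[-i, , drop = FALSE])
    sum(c(1, X[i, ]) * coef(fit))
  }, numeric(1))
  expect_equal(pred, refit)
})

test_that("LOOCV has no leakage: y_i never influences its own prediction", {
  X <- withr::with_seed(4, matrix(rnorm(60), 20, 3))
  y <- withr::with_seed(5, rnorm(20))
  p1 <- loocv_predict(X, y)
  y2 <- y; y2[7] <- y2[7] + 100
  p2 <- loocv_predict(X, y2)
  expect_equal(p2[7], p1[7])
  expect_false(any(abs(p2[-7] - p1[-7]) < 1e-12))
})

test_that("rank-deficient designs raise errors rather than regularize", {
  X <- withr::with_seed(6, matrix(rnorm(40), 20, 2))
  expect_error(loocv_predict(cbind(X, X[, 1]), rnorm(20)),
               class = "stopnet_rank_error")
  expect_error(loocv_predict(matrix(rnorm(40), 20, 2), rnorm(5)),
               class = "stopnet_param_error")
})

test_that("LOOCV accuracy under pure noise shows the mean-reversion bias", {
  # under the null the leave-one-out prediction moves opposite to the held-out
  # value (intercept-only: r = -1 exactly), so corr(pred, y) is negative on
  # average, not zero; verify against an explicit refit-loop oracle
  rs <- vapply(1:300, function(s) {
    withr::with_seed(10000 + s, {
      X <- matrix(rnorm(20 * 2), 20, 2)
      y <- rnorm(20)
      cor(loocv_predict(X, y), y)
    })
  }, numeric(1))
  oracle <- vapply(1:60, function(s) {
    withr::with_seed(10000 + s, {
      X <- matrix(rnorm(20 * 2), 20, 2)
      y <- rnorm(20)
    })
    pred <- vapply(1:20, function(i) {
      sum(c(1, X[i, ]) * coef(lm(y[-i] ~ X[-i, , drop = FALSE])))
    }, numeric(1))
    cor(pred, y)
  }, numeric(1))
  expect_lt(mean(rs), 0)
  expect_equal(rs[1:60], oracle)
  expect_lt(abs(mean(rs) - mean(oracle)), 0.12)
})

test_that("partial correlation equals the two-stage residual computation", {
  a <- c(3, 1, 4, 1, 5); b <- c(2, 7, 1, 8, 2); z <- c(1, 2, 3, 4, 5)
  manual <- cor(resid(lm(a ~ z)), resid(lm(b ~ z)))
  expect_equal(partial_pearson(a, b, z), manual)
  # constant covariate reduces to the plain correlation
  expect_equal(partial_pearson(a, b, rep(2, 5)), cor(a, b))
  expect_equal(partial_pearson(a, a, z), 1)
  expect_error(partial_pearson(a, z, z), class = "stopnet_input_error")
})

test_that("permutation p-values are deterministic, smoothed, and affine-invariant", {
  withr::with_seed(11, {
    X <- matrix(rnorm(30 * 2), 30, 2)
    y <- X[, 1] + rnorm(30, sd = 0.5)
    z <- rnorm(30)
  })
  p1 <- permutation_pvalue(X, y, z, n_iter = 300, seed = 42)
  p2 <- permutation_pvalue(X, y, z, n_iter = 300, seed = 42)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$null, p2$null)
  # +1 smoothing: p in [1/(n_iter+1), 1]
  expect_gte(p1$p_value, 1 / 301)
  expect_lte(p1$p_value, 1)
  expect_equal(p1$p_value, (1 + sum(p1$null >= p1$statistic)) / 301)
  # affine rescaling of y leaves the Pearson statistic and p unchanged
  p3 <- permutation_pvalue(X, 3 * y + 100, z, n_iter = 300, seed = 42)
  expect_equal(p3$statistic, p1$statistic, tolerance = 1e-12)
  expect_equal(p3$p_value, p1$p_value)
  expect_warning(permutation_pvalue(X, y, z, n_iter = 50, seed = 1),
                 "unstable")
})

test_that("an observed statistic no larger than the whole null gives p = 1", {
  # intercept-only model: the leave-one-out prediction is (sum(y) - y_i)/(n-1),
  # a decreasing affine function of y_i, so the partial r is exactly -1 for
  # the observed y and every permutation alike - the boundary case
  withr::with_seed(12, {
    y <- rnorm(25)
    z <- rnorm(25)
  })
  perm <- permutation_pvalue(matrix(nrow = 25, ncol = 0), y, z,
                             n_iter = 200, seed = 9)
  expect_equal(perm$statistic, -1)
  expect_equal(perm$p_value, 1)
})

test_that("Bayes factor matches an independent quadrature oracle", {
  # trapezoid integration of the same exact r-density at high resolution,
  # written independently of the package's integrate() path
  bf_trap <- function(r, n) {
    rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 40001)
    dens <- vapply(rho, function(p) {
      lf <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-p^2) +
        ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
        (n - 1.5) * log1p(-p * r)
      z <- (p * r + 1) / 2
      term <- 1; tot <- 1
      for (k in 1:5000) {
        term <- term * (0.5 + k - 1)^2 / ((n - 0.5 + k - 1) * k) * z
        tot <- tot + term
        if (term < 1e-14 * tot) break
      }
      exp(lf) * tot
    }, numeric(1))
    h <- rho[2] - rho[1]
    marg <- (sum(dens) - (dens[1] + dens[length(dens)]) / 2) * h / 2
    marg / dens[which.min(abs(rho))]
  }
  expect_equal(bf10_correlation(0.3, 50), bf_trap(0.3, 50), tolerance = 1e-4)
  expect_equal(bf10_correlation(-0.2, 30), bf_trap(-0.2, 30), tolerance = 1e-4)
})

test_that("Bayes factor behaves like evidence", {
  # nil-consistent data favor the null
  expect_lt(bf10_correlation(0, 141), 1)
  # monotone in |r| at fixed n
  rs <- seq(0, 0.6, by = 0.1)
  bfs <- vapply(rs, bf10_correlation, numeric(1), n = 60)
  expect_true(all(diff(bfs) > 0))
  expect_identical(bf10_correlation(1, 20), Inf)
  # one-sided evidence doubles for positive r under the uniform prior
  expect_gt(bf10_correlation(0.3, 50, sided = "positive"),
            bf10_correlation(0.3, 50))
})

test_that("correlation Bayes factors order as the reported pair", {
  bf_a <- bf10_correlation(0.211, 141)
  bf_b <- bf10_correlation(0.185, 141)
  expect_gt(bf_a, bf_b)
  expect_gt(bf_a, 1)
  expect_gt(bf_b, 1)
  # under the one-sided variant the pair splits across the moderate (>3)
  # and anecdotal (1-3) evidence bands
  bf_a1 <- bf10_correlation(0.211, 141, sided = "positive")
  bf_b1 <- bf10_correlation(0.185, 141, sided = "positive")
  expect_gt(bf_a1, 3)
  expect_true(bf_b1 > 1 && bf_b1 < 3)
})

test_that("post-hoc power hits alpha at R2 = 0 and is monotone", {
  expect_equal(posthoc_power(0, 141, 12), 0.05)
  expect_equal(posthoc_power(0, 141, 12, alpha = 0.2), 0.2)
  r2s <- seq(0, 0.5, by = 0.05)
  pw <- vapply(r2s, posthoc_power, numeric(1), n = 141, k = 12)
  expect_true(all(diff(pw) > 0))
  ns <- seq(30, 300, by = 30)
  pw_n <- vapply(ns, function(n) posthoc_power(0.15, n, 12), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  expect_gt(posthoc_power(0.15, 141, 12, alpha = 0.1),
            posthoc_power(0.15, 141, 12, alpha = 0.01))
  expect_gt(posthoc_power(0.3, 10000, 12), 0.9999)
  # df-adjusted convention is strictly less powerful
  expect_lt(posthoc_power(0.15, 141, 12, ncp = "df"),
            posthoc_power(0.15, 141, 12, ncp = "n"))
  expect_error(posthoc_power(0.5, 10, 12), class = "stopnet_param_error")
})

test_that("post-hoc power matches a Monte-Carlo noncentral-F oracle", {
  n <- 141; k <- 12; R2 <- 0.15
  f2 <- R2 / (1 - R2)
  draws <- withr::with_seed(77, stats::rf(40000, k, n - k - 1, ncp = f2 * n))
  crit <- qf(0.95, k, n - k - 1)
  mc <- mean(draws > crit)
  expect_equal(posthoc_power(R2, n, k), mc, tolerance = 0.02)
})
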