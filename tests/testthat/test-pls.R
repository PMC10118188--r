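test_that("at k = rank(X) the PLS fit equals least squares", {
  set.seed(1)
  for (dims in list(c(12, 3), c(25, 5), c(40, 7))) {
    n <- dims[1]; p <- dims[2]
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_pls(X, y, k = p)
    ols <- lm(y ~ X)
    expect_equal(m$fitted, unname(fitted(ols)), tolerance = 1e-8)
    expect_equal(unname(m$coefficients), unname(coef(ols)[-1]),
                 tolerance = 1e-8)
    expect_equal(m$residuals, unname(resid(ols)), tolerance = 1e-8)
  }
})

test_that("univariate k = 1 coefficient is the standardized slope", {
  set.seed(2)
  x <- rnorm(15); y <- 2 * x + rnorm(15)
  m <- fit_pls(matrix(x), y, k = 1)
  slope_std <- cor(x, y)                 # slope on standardized scales
  expect_equal(unname(m$coefficients_std), slope_std, tolerance = 1e-10)
})

test_that("rank-1 exactly representable response has zero residuals", {
  set.seed(3)
  x <- rnorm(10)
  X <- cbind(x, 2 * x + 1e-9 * rnorm(10))    # (numerically) rank ~1
  y <- 3 * x + 1
  m <- fit_pls(X, y, k = 1)
  expect_lt(max(abs(m$residuals)), 1e-6)
})

test_that("R2 is non-decreasing in k; k beyond rank is rejected", {
  set.seed(4)
  X <- matrix(rnorm(20 * 4), 20)
  y <- rnorm(20)
  r2 <- vapply(1:4, function(k) fit_pls(X, y, k)$R2, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  Xdef <- cbind(X[, 1], X[, 1], X[, 2])          # rank 2
  expect_error(fit_pls(Xdef, y, k = 3), "rank")
})

test_that("fits are invariant to observation order", {
  set.seed(5)
  X <- matrix(rnorm(18 * 3), 18)
  y <- rnorm(18)
  m1 <- fit_pls(X, y, k = 2)
  perm <- sample(18)
  m2 <- fit_pls(X[perm, ], y[perm], k = 2)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  expect_equal(m1$fitted[perm], m2$fitted, tolerance = 1e-10)
})

test_that("LOO curves match a naive double-loop oracle to 1e-10", {
  set.seed(6)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- as.numeric(X %*% c(1, -1, 0.5)) + rnorm(12, sd = 0.5)
  cv <- loo_cv(X, y, k_max = 3)
  ref <- oracle_loo_rmsecv(X, y, k_max = 3)
  expect_equal(cv$rmsecv, ref$rmsecv, tolerance = 1e-10)
  expect_equal(cv$r2cv, ref$r2cv, tolerance = 1e-10)
})

test_that("R2CV of an unpredictable response is non-positive", {
  set.seed(7)
  X <- matrix(rnorm(20 * 3), 20)
  y <- 5 + rnorm(20, sd = 1e-3)          # constant + tiny noise
  cv <- loo_cv(X, y, k_max = 3)
  expect_true(all(cv$r2cv <= 0))
})

test_that("an extreme outlier makes RMSECV exceed in-sample RMSE", {
  set.seed(8)
  X <- matrix(rnorm(15 * 2), 15)
  y <- as.numeric(X %*% c(1, 1)) + rnorm(15, sd = 0.1)
  y[4] <- y[4] + 25
  cv <- loo_cv(X, y, k_max = 2)
  m <- fit_pls(X, y, k = 2)
  rmse_in <- sqrt(mean(m$residuals^2))
  expect_gt(cv$rmsecv[2], rmse_in)
})

test_that("select_k applies the slope rule, capped at the minimum", {
  expect_equal(select_k(c(1.00, 0.50, 0.49, 0.49)), 2)
  expect_equal(select_k(c(0.5, 0.6, 0.7)), 1)       # strictly increasing
  expect_equal(select_k(c(0.4, 0.6, 0.3)), 1)       # capped... min first?
  expect_equal(select_k(c(0.3, 0.6, 0.5)), 1)       # min at first element
  expect_equal(select_k(0.7), 1)                    # length-1 curve
  ## threshold is tunable
  expect_equal(select_k(c(1, 0.9, 0.89), tau = 0.2), 1)
})
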