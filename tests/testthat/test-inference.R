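test_that("noiseless responses give zero jackknife variance + flag", {
  set.seed(30)
  X <- matrix(rnorm(15 * 3), 15)
  y <- as.numeric(X %*% c(1, 2, -1)) + 4
  j <- wu_jackknife(X, y, k = 3)
  expect_true(j$degenerate)
  expect_true(all(j$table$variance < 1e-16))
  expect_true(all(j$table$p_value == 0))
})

test_that("at k = rank(X) Wu variances match the delete-one OLS oracle", {
  set.seed(31)
  for (i in 1:3) {
    n <- 20 + 5 * i; p <- 3
    X <- matrix(rnorm(n * p), n)
    y <- as.numeric(X %*% rnorm(p)) + rnorm(n, sd = 0.5 + i / 4)
    j <- wu_jackknife(X, y, k = p)
    expect_equal(j$table$variance, unname(oracle_wu_ols(X, y)),
                 tolerance = 1e-8)
  }
})

test_that("null rejection rate is calibrated against the OLS oracle", {
  ## y independent of X at k = rank: the PLS jackknife t-test and an
  ## identically-defined delete-one OLS test target the same rate;
  ## estimate both on independent replicate streams and compare within
  ## joint binomial 99% bounds (scaled-down replicate count)
  n <- 40; p <- 3; n_rep <- 250; alpha <- 0.05
  rej_impl <- 0; rej_ref <- 0
  set.seed(32)
  for (r in seq_len(n_rep)) {
    X1 <- matrix(rnorm(n * p), n); y1 <- rnorm(n)
    j <- wu_jackknife(X1, y1, k = p)
    rej_impl <- rej_impl + (j$table$p_value[1] < alpha)

    X2 <- matrix(rnorm(n * p), n); y2 <- rnorm(n)
    v <- oracle_wu_ols(X2, y2)
    b <- coef(lm(y2 ~ X2))[-1]
    tt <- b[1] / sqrt(v[1])
    p_ref <- 2 * pt(-abs(tt), n - p - 1)
    rej_ref <- rej_ref + (p_ref < alpha)
  }
  rate_impl <- rej_impl / n_rep
  rate_ref <- rej_ref / n_rep
  se <- sqrt(rate_ref * (1 - rate_ref) / n_rep +
               rate_impl * (1 - rate_impl) / n_rep)
  expect_lt(abs(rate_impl - rate_ref), 2.58 * max(se, 0.01))
})

test_that("zero-residual wild bootstrap gives zero-width intervals", {
  set.seed(33)
  X <- matrix(rnorm(12 * 2), 12)
  y <- as.numeric(X %*% c(1, -2)) + 3
  wb <- wild_bootstrap(X, y, k = 2, n_resamples = 50, seed = 9)
  expect_equal(wb$coef_ci$lower, wb$coef_ci$upper, tolerance = 1e-10)
  expect_equal(wb$cell_ci$lower, wb$cell_ci$upper, tolerance = 1e-10)
})

test_that("at k = rank(X) wild-bootstrap CIs match the OLS oracle on shared streams", {
  set.seed(34)
  n <- 24; p <- 3
  X <- matrix(rnorm(n * p), n)
  ## heteroscedastic noise
  y <- as.numeric(X %*% c(1, 0, -1)) + rnorm(n, sd = 0.3 + abs(X[, 1]))
  wb <- wild_bootstrap(X, y, k = p, n_resamples = 400, seed = 77)
  ref <- oracle_wild_ols(X, y, n_resamples = 400, seed = 77)
  expect_equal(wb$coef_ci$lower, unname(ref[, 1]), tolerance = 1e-8)
  expect_equal(wb$coef_ci$upper, unname(ref[, 2]), tolerance = 1e-8)
})

test_that("wild bootstrap default resample count is 2000", {
  expect_equal(eval(formals(wild_bootstrap)$n_resamples), 2000)
})

test_that("wild bootstrap is deterministic given the seed", {
  set.seed(35)
  X <- matrix(rnorm(15 * 2), 15)
  y <- rnorm(15)
  a <- wild_bootstrap(X, y, k = 2, n_resamples = 100, seed = 5)
  b <- wild_bootstrap(X, y, k = 2, n_resamples = 100, seed = 5)
  expect_identical(a$coef_ci, b$coef_ci)
  expect_identical(a$cell_ci, b$cell_ci)
})

test_that("compare_cells uses strict disjointness", {
  rep0 <- list(cell_ci = data.frame(
    cell = c("a", "b", "c", "d"),
    predicted = c(1.5, 3.5, 2, 2.5),
    lower = c(1, 3, 1, 2), upper = c(2, 4, 3, 3)))
  expect_true(compare_cells(rep0, "a", "b"))      # [1,2] vs [3,4]
  expect_false(compare_cells(rep0, "c", "d"))     # [1,3] vs [2,4]
  ## shared endpoint intersects
  rep1 <- list(cell_ci = data.frame(cell = c("a", "b"),
                                    predicted = c(1, 2),
                                    lower = c(1, 2), upper = c(2, 3)))
  expect_false(compare_cells(rep1, "a", "b"))
  expect_error(compare_cells(rep0, "a", "zz"), "not present")
})

test_that("letter displays cover the canonical cases", {
  mk <- function(pred, lo, hi) {
    data.frame(cell = paste0("c", seq_along(pred)), predicted = pred,
               lower = lo, upper = hi)
  }
  ## all overlapping -> everyone A
  ld <- letter_display(mk(c(3, 2, 1), c(0, 0, 0), c(4, 4, 4)))
  expect_true(all(ld$letters == "A"))
  ## pairwise disjoint -> A, B, C with A on the largest
  ld <- letter_display(mk(c(1, 3, 2), c(0.5, 2.6, 1.6),
                          c(1.5, 3.4, 2.4)))
  expect_equal(ld$letters[order(-ld$predicted)], c("A", "B", "C"))
  expect_equal(ld$cell[ld$letters == "A"], "c2")
  ## chain: x > y > z, (x,y) and (y,z) overlap, (x,z) disjoint
  ld <- letter_display(mk(c(3, 2, 1), c(2.5, 1.8, 0.5),
                          c(3.5, 2.9, 1.9)))
  expect_equal(ld$letters, c("A", "AB", "B"))
})

test_that("letter soundness holds on random interval families", {
  set.seed(36)
  for (i in 1:40) {
    m <- sample(3:8, 1)
    ctr <- rnorm(m, sd = 2)
    hw <- runif(m, 0.2, 2)
    df <- data.frame(cell = paste0("c", seq_len(m)), predicted = ctr,
                     lower = ctr - hw, upper = ctr + hw)
    ld <- letter_display(df)      # self-asserts share-iff-overlap
    expect_true(all(nzchar(ld$letters)))
  }
})

test_that("widening all intervals never creates significance", {
  set.seed(37)
  for (i in 1:20) {
    m <- 5
    ctr <- rnorm(m, sd = 2); hw <- runif(m, 0.2, 1.5)
    narrow <- list(cell_ci = data.frame(
      cell = paste0("c", 1:m), predicted = ctr,
      lower = ctr - hw, upper = ctr + hw))
    wide <- list(cell_ci = data.frame(
      cell = paste0("c", 1:m), predicted = ctr,
      lower = ctr - 2 * hw, upper = ctr + 2 * hw))
    for (a in 1:(m - 1)) {
      for (b in (a + 1):m) {
        ca <- paste0("c", a); cb <- paste0("c", b)
        if (!compare_cells(narrow, ca, cb)) {
          expect_false(compare_cells(wide, ca, cb))
        }
      }
    }
  }
})

test_that("letter alphabet extends past 26 groups", {
  labs <- streambaci:::letter_labels(30)
  expect_equal(labs[26], "Z")
  expect_equal(labs[27], "AA")
  expect_equal(length(unique(labs)), 30)
})

test_that("coefficient-CI and jackknife t-test agree on strong signals", {
  set.seed(38)
  agree <- 0; total <- 0
  for (i in 1:10) {
    n <- 60; p <- 3
    X <- matrix(rnorm(n * p), n)
    y <- as.numeric(X %*% c(2, 0, -2)) + rnorm(n)
    j <- wu_jackknife(X, y, k = p)
    wb <- wild_bootstrap(X, y, k = p, n_resamples = 300, seed = i)
    sig_j <- j$table$p_value < 0.05
    total <- total + p
    agree <- agree + sum(sig_j == wb$coef_ci$significant)
  }
  expect_gt(agree / total, 0.85)
})
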