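## Independent oracles used across the suite. Each is coded from the
## defining formula, on a different route than the implementation it
## checks, and stays out of the package's own code paths.

## --- PLS1 via the Krylov-projection characterization ------------------
## Coefficients after k components solve the least-squares problem
## restricted to the Krylov space span{s, Ss, ..., S^{k-1} s} with
## S = X'X, s = X'y (data already centered/scaled).
oracle_pls_coef <- function(Xs, ys, k) {
  S <- crossprod(Xs)
  s <- crossprod(Xs, ys)
  V <- matrix(NA_real_, ncol(Xs), k)
  v <- s
  for (j in seq_len(k)) {
    V[, j] <- v
    v <- S %*% v
  }
  Q <- qr.Q(qr(V))
  as.numeric(Q %*% solve(crossprod(Q, S %*% Q), crossprod(Q, s)))
}

oracle_pls_fitted <- function(Xs, ys, k) {
  as.numeric(Xs %*% oracle_pls_coef(Xs, ys, k))
}

## naive standardization (its own code, same n-1 convention)
oracle_standardize <- function(X, y) {
  mx <- apply(X, 2, mean)
  sx <- sqrt(apply(sweep(X, 2, mx)^2, 2, sum) / (nrow(X) - 1))
  my <- mean(y)
  sy <- sqrt(sum((y - my)^2) / (length(y) - 1))
  list(Xs = sweep(sweep(X, 2, mx), 2, sx, "/"), ys = (y - my) / sy,
       mx = mx, sx = sx, my = my, sy = sy)
}

## --- naive double-loop leave-one-out CV -------------------------------
oracle_loo_rmsecv <- function(X, y, k_max) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, k_max)
  for (k in seq_len(k_max)) {
    for (i in seq_len(n)) {
      st <- oracle_standardize(X[-i, , drop = FALSE], y[-i])
      b <- oracle_pls_coef(st$Xs, st$ys, k)
      xn <- (X[i, ] - st$mx) / st$sx
      pred[i, k] <- sum(xn * b) * st$sy + st$my
    }
  }
  list(rmsecv = sqrt(colMeans((y - pred)^2)),
       r2cv = 1 - colSums((y - pred)^2) / sum((y - mean(y))^2))
}

## --- exact KS2 p by brute-force enumeration of label assignments ------
oracle_ks2_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  Dstat <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(v) mean(a <= v) - mean(b <= v),
                   numeric(1))))
  }
  D_obs <- Dstat(x, y)
  combs <- utils::combn(n + m, n)
  hits <- 0L
  for (ci in seq_len(ncol(combs))) {
    ix <- combs[, ci]
    if (Dstat(pooled[ix], pooled[-ix]) >= D_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combs)
}

## --- BCa interval from the defining formulas, shared RNG stream -------
oracle_bca <- function(sample, alpha, n_boot, seed) {
  n <- length(sample)
  th <- mean(sample)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  stars <- apply(idx, 2, function(ix) mean(sample[ix]))
  prop <- sum(stars < th) / n_boot
  prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- qnorm(prop)
  tj <- sapply(seq_len(n), function(i) mean(sample[-i]))
  d <- mean(tj) - tj
  a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  q7 <- function(v, p) {            # hand-coded type-7 quantile
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  c(q7(stars, adj(qnorm(alpha / 2))), q7(stars, adj(qnorm(1 - alpha / 2))))
}

## --- Wu leverage-weighted delete-one jackknife on OLS -----------------
oracle_wu_ols <- function(X, y) {
  n <- nrow(X)
  fit <- lm(y ~ X)
  h <- unname(lm.influence(fit)$hat)
  b <- coef(fit)[-1]
  Bd <- sapply(seq_len(n), function(i) {
    coef(lm(y[-i] ~ X[-i, , drop = FALSE]))[-1]
  })
  Bd <- matrix(Bd, nrow = length(b))
  rowSums(sweep((Bd - b)^2, 2, 1 - h, "*"))
}

## --- HC3 wild bootstrap on OLS, shared sign stream --------------------
oracle_wild_ols <- function(X, y, n_resamples, seed, alpha = 0.05) {
  n <- nrow(X)
  fit <- lm(y ~ X)
  h <- unname(lm.influence(fit)$hat)
  e <- resid(fit) / (1 - h)
  f <- fitted(fit)
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n * n_resamples, replace = TRUE), n)
  B <- sapply(seq_len(n_resamples), function(b) {
    coef(lm((f + e * S[, b]) ~ X))[-1]
  })
  B <- matrix(B, nrow = ncol(X))
  q7 <- function(v, p) {
    v <- sort(v)
    hh <- (length(v) - 1) * p + 1
    lo <- floor(hh)
    v[lo] + (hh - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  t(apply(B, 1, function(v) c(q7(v, alpha / 2), q7(v, 1 - alpha / 2))))
}

## --- central finite-difference trace of the fitted-value Jacobian -----
oracle_fd_trace <- function(Xs, ys, k, eps = 1e-5) {
  n <- length(ys)
  tr <- 0
  for (i in seq_len(n)) {
    e <- rep(0, n); e[i] <- eps
    tr <- tr + (oracle_pls_fitted(Xs, ys + e, k)[i] -
                  oracle_pls_fitted(Xs, ys - e, k)[i]) / (2 * eps)
  }
  tr
}

## --- small simulated factorial fixture --------------------------------
make_factorial_fixture <- function(n_per_cell = 3, a = 4, b = 2,
                                   beta_sd = 1, noise = 0.3, seed = 1) {
  set.seed(seed)
  f1 <- factor(rep(paste0("g", seq_len(a)), each = b * n_per_cell))
  f2 <- factor(rep(rep(c("pre", "post"), each = n_per_cell), a),
               levels = c("pre", "post"))
  X <- build_design(list(Treatment = f1, Period = f2))
  y <- as.numeric(X %*% rnorm(ncol(X), sd = beta_sd)) +
    rnorm(length(f1), sd = noise)
  list(X = unclass_design(X), y = y, f1 = f1, f2 = f2)
}

unclass_design <- function(X) {
  attr(X, "factor_map") <- NULL
  class(X) <- NULL
  X
}
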