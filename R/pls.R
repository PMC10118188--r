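## PLS1 (single-response partial least squares) core.
##
## NIPALS on centered/scaled data. For a univariate response NIPALS and
## SIMPLS produce identical models; NIPALS is used because the coefficient
## path for k = 1..kmax falls out of one pass, which the LOO loop exploits.

## Xs, ys already centered/scaled. Returns weights/loadings/scores and the
## coefficient path B (p x kmax_reached) on the standardized scale.
pls_path <- function(Xs, ys, kmax, tol = 1e-12) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs); p <- ncol(Xs)
  kmax <- min(kmax, p)
  W <- matrix(0, p, kmax); P <- matrix(0, p, kmax)
  Tm <- matrix(0, n, kmax); q <- numeric(kmax)
  X1 <- Xs; y1 <- ys
  k_eff <- 0L
  for (a in seq_len(kmax)) {
    w <- crossprod(X1, y1)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_a <- X1 %*% w
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(X1, t_a) / tt
    q_a <- sum(y1 * t_a) / tt
    X1 <- X1 - t_a %*% t(p_a)
    y1 <- y1 - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    k_eff <- a
  }
  if (k_eff == 0L) stop("response is orthogonal to all regressors")
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  Tm <- Tm[, seq_len(k_eff), drop = FALSE]
  q <- q[seq_len(k_eff)]
  ## B_k = W_k (P_k' W_k)^{-1} q_k for each k (P'W is upper bidiagonal)
  B <- matrix(0, p, k_eff)
  PtW <- crossprod(P, W)
  for (k in seq_len(k_eff)) {
    sol <- solve(PtW[seq_len(k), seq_len(k), drop = FALSE], q[seq_len(k)])
    B[, k] <- W[, seq_len(k), drop = FALSE] %*% sol
  }
  list(W = W, P = P, T = Tm, q = q, B = B, k = k_eff)
}

#' Fit a centered/scaled PLS regression
#'
#' Fits a deterministic univariate-response PLS model with `k` latent
#' variables on centered and scaled regressors and response (NIPALS;
#' identical to SIMPLS for one response). Coefficients are reported both
#' on the standardized scale and back-transformed to the (possibly
#' Box-Cox transformed) response scale; fitted values and predictions are
#' on the response scale.
#'
#' @param X Design matrix (see [build_design()]) or numeric matrix.
#' @param y Numeric response vector.
#' @param k Number of latent variables, `1 <= k <= ncol(X)`; components
#'   beyond the rank of the centered `X` are rejected.
#' @return Object of class `pls_model`: list with `k`, `coefficients`
#'   (response scale), `coefficients_std`, `intercept`, `fitted`,
#'   `residuals`, `R2`, centering/scaling constants, and the NIPALS
#'   weights/loadings/scores.
#' @export
fit_pls <- function(X, y, k) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (k < 1 || k > ncol(X)) stop("k must be in 1..ncol(X)")
  if (n < k + 2) stop("need n >= k + 2 observations")
  cs <- center_scale(X, y)
  path <- pls_path(cs$X, cs$y, kmax = k)
  if (path$k < k) {
    stop(sprintf("k = %d exceeds the effective rank (%d) of the design",
                 k, path$k))
  }
  b_std <- path$B[, k]
  b_orig <- b_std * cs$y_scale / cs$x_scale
  intercept <- cs$y_center - sum(b_orig * cs$x_center)
  fitted <- as.numeric(X %*% b_orig + intercept)
  res <- y - fitted
  structure(list(
    k = k, coefficients = stats::setNames(b_orig, colnames(X)),
    coefficients_std = stats::setNames(b_std, colnames(X)),
    intercept = intercept, fitted = fitted, residuals = res,
    R2 = 1 - sum(res^2) / sum((y - mean(y))^2),
    x_center = cs$x_center, x_scale = cs$x_scale,
    y_center = cs$y_center, y_scale = cs$y_scale,
    weights = path$W, loadings = path$P, scores = path$T, q = path$q,
    X = X, y = y), class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Full (leave-one-out) cross-validation: each observation is predicted
#' from a model fit without it, with centering and scaling re-estimated
#' inside each fold, for every component count `k = 1..k_max`. Returns the
#' RMSECV and R2CV curves from the pooled held-out predictions; R2CV can
#' be negative. A fold in which a design column loses all variance is
#' flagged (the column is dropped from that fold's standardization by
#' freezing its scale at 1 and its centered values at 0).
#'
#' @param X Numeric design matrix.
#' @param y Response vector (length >= 3).
#' @param k_max Largest component count to evaluate (capped at `ncol(X)`).
#' @return List with `rmsecv` and `r2cv` (length `k_max` vectors),
#'   `predictions` (n x k_max matrix of held-out predictions) and
#'   `flagged_folds`.
#' @export
loo_cv <- function(X, y, k_max = ncol(X)) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need n >= 3 for leave-one-out CV")
  k_max <- min(k_max, ncol(X))
  pred <- matrix(NA_real_, n, k_max)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xc <- colMeans(Xi)
    xs <- apply(Xi, 2, stats::sd)
    dead <- which(xs <= 0 | !is.finite(xs))
    if (length(dead) > 0L) {
      flagged <- c(flagged, i)
      xs[dead] <- 1
    }
    Xsi <- sweep(sweep(Xi, 2, xc), 2, xs, "/")
    if (length(dead) > 0L) Xsi[, dead] <- 0
    yc <- mean(yi); ysc <- stats::sd(yi)
    if (ysc <= 0) ysc <- 1
    path <- pls_path(Xsi, (yi - yc) / ysc, kmax = k_max)
    xnew <- (X[i, ] - xc) / xs
    if (length(dead) > 0L) xnew[dead] <- 0
    pr_std <- crossprod(path$B, xnew)          # one value per k available
    kk <- min(k_max, path$k)
    pred[i, seq_len(kk)] <- pr_std[seq_len(kk)] * ysc + yc
    if (kk < k_max) pred[i, (kk + 1L):k_max] <- pred[i, kk]
  }
  press <- colSums((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(rmsecv = sqrt(press / n), r2cv = 1 - press / tss,
       predictions = pred, flagged_folds = flagged)
}

#' Select the number of latent variables from an RMSECV curve
#'
#' Operationalizes "a notable change in slope of the RMSECV graph,
#' usually at or near the minimum": the smallest `k` at which the relative
#' improvement from `k` to `k + 1`,
#' `(rmsecv[k] - rmsecv[k+1]) / rmsecv[k]`, drops to `tau` or below,
#' capped at the global-minimum `k`. A length-1 curve returns 1.
#'
#' @param rmsecv_curve Numeric vector of RMSECV values for k = 1, 2, ...
#' @param tau Relative-improvement threshold (default 0.02).
#' @return Integer component count.
#' @export
select_k <- function(rmsecv_curve, tau = 0.02) {
  stopifnot(length(rmsecv_curve) >= 1L)
  if (length(rmsecv_curve) == 1L) return(1L)
  k_sel <- length(rmsecv_curve)
  for (k in seq_len(length(rmsecv_curve) - 1L)) {
    rel <- (rmsecv_curve[k] - rmsecv_curve[k + 1L]) / rmsecv_curve[k]
    if (rel <= tau + 1e-12) { k_sel <- k; break }
  }
  min(k_sel, which.min(rmsecv_curve))
}
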