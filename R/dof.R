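## Degrees of freedom of PLS1 via the trace of the fitted-value Jacobian.
##
## For centered/scaled data, the PLS1 fitted values after m components are
## the orthogonal projection of y onto the Krylov image space
## span{Ay, A^2 y, ..., A^m y} with A = X X'. Writing yhat = T T' y with T
## an orthonormal (Arnoldi) basis of that space, the basis itself depends
## on y, so DoF(m) = trace(d yhat / d y) generally exceeds m. The Jacobian
## is propagated exactly through the Arnoldi recursion: this is the
## unbiased degrees-of-freedom estimate of the Krylov-space formulation,
## and it collapses to rank(X) (the least-squares value) when m saturates
## the rank.

## Returns J = d(yhat)/d(y) (n x n), the scores basis T, and the number of
## components actually realized (Krylov breakdown truncates).
pls_fitted_jacobian <- function(Xs, ys, k, tol = 1e-10) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs)
  A <- tcrossprod(Xs)                      # X X'
  y <- as.numeric(ys)
  Tm <- matrix(0, n, k)
  Jt <- vector("list", k)
  k_eff <- 0L
  warn_cond <- FALSE
  for (i in seq_len(k)) {
    if (i == 1L) {
      v <- A %*% y
      Jv <- A
    } else {
      v <- A %*% Tm[, i - 1L]
      Jv <- A %*% Jt[[i - 1L]]
    }
    ## modified Gram-Schmidt against previous basis vectors, with
    ## product-rule updates of the Jacobian
    if (k_eff > 0L) {
      for (j in seq_len(k_eff)) {
        tj <- Tm[, j]
        coef <- sum(tj * v)
        Jv <- Jv - tj %*% (crossprod(tj, Jv)) -
          coef * Jt[[j]] - tj %*% (crossprod(v, Jt[[j]]))
        v <- v - coef * tj
      }
    }
    s <- sqrt(sum(v^2))
    if (s < tol * max(1, sqrt(sum(diag(A))))) break
    if (s < 1e-7) warn_cond <- TRUE
    t_i <- as.numeric(v / s)
    Jt[[i]] <- (diag(n) - tcrossprod(t_i)) %*% Jv / s
    Tm[, i] <- t_i
    k_eff <- i
  }
  if (k_eff == 0L) stop("Krylov space is empty (y orthogonal to X)")
  if (warn_cond) warning("numerically singular Krylov basis; ",
                         "DoF may be ill-conditioned")
  J <- matrix(0, n, n)
  for (i in seq_len(k_eff)) {
    t_i <- Tm[, i]
    J <- J + tcrossprod(t_i) + sum(t_i * y) * Jt[[i]] +
      t_i %*% (crossprod(y, Jt[[i]]))
  }
  list(J = J, T = Tm[, seq_len(k_eff), drop = FALSE], k = k_eff)
}

#' Degrees of freedom of a fitted PLS model
#'
#' Unbiased degrees-of-freedom estimate for PLS regression: the trace of
#' the derivative of the fitted values with respect to the response,
#' computed exactly through the Krylov-space recursion that generates the
#' PLS1 fit, plus 1 for the intercept (centering). At `k = rank(X)` PLS
#' saturates to least squares and the DoF equals `rank(X) + 1`. The
#' response-scaling constant is treated as fixed in the derivative.
#'
#' @param model A `pls_model` from [fit_pls()] (or NULL to pass raw data).
#' @param X,y Raw design matrix and response (used when `model` is NULL;
#'   otherwise taken from the model).
#' @param k Component count (defaults to the model's `k`).
#' @return DoF as a single numeric value in `[1, n]`.
#' @export
pls_dof <- function(model = NULL, X = NULL, y = NULL, k = NULL) {
  if (!is.null(model)) {
    X <- model$X; y <- model$y
    if (is.null(k)) k <- model$k
  }
  cs <- center_scale(X, y)
  jac <- pls_fitted_jacobian(cs$X, cs$y, k)
  dof <- 1 + sum(diag(jac$J))
  min(max(dof, 1), length(y))
}

#' Linearized leverage of a fitted PLS model
#'
#' Diagonal of the hat operator implied by the fitted-value Jacobian at
#' the solution, including the 1/n contribution of centering. At
#' `k = rank(X)` this reduces to the ordinary least-squares hat diagonal
#' (with intercept). Used by the HC3 wild bootstrap and the Wu jackknife.
#'
#' @inheritParams pls_dof
#' @return Numeric vector of length n.
#' @export
pls_leverage <- function(model = NULL, X = NULL, y = NULL, k = NULL) {
  if (!is.null(model)) {
    X <- model$X; y <- model$y
    if (is.null(k)) k <- model$k
  }
  cs <- center_scale(X, y)
  jac <- pls_fitted_jacobian(cs$X, cs$y, k)
  h <- 1 / length(y) + diag(jac$J)
  pmin(pmax(h, 0), 1 - 1e-8)
}
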