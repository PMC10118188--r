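#' Box-Cox power transformation
#'
#' \eqn{y^{(\lambda)} = (y^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0}
#' and \eqn{\log y} at \eqn{\lambda = 0} (the continuous limit). A
#' non-negative `shift` is added before transforming so shifted values are
#' strictly positive.
#'
#' @param y Numeric vector.
#' @param lambda Power exponent (`lambda = 1`, `shift = 0` is an affine
#'   map of the raw data).
#' @param shift Non-negative shift added before transforming.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(y, lambda, shift = 0) {
  ys <- y + shift
  if (any(ys <= 0)) stop("shifted values must be strictly positive")
  if (abs(lambda) < 1e-12) log(ys) else (ys^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param z Values on the transformed scale.
#' @export
boxcox_inverse <- function(z, lambda, shift = 0) {
  y <- if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
  y - shift
}

## default shift: 0 unless data contain non-positive values
boxcox_default_shift <- function(y) {
  if (min(y) > 0) 0 else abs(min(y)) + 1e-6 * max(abs(y), 1)
}

#' Search for a response transformation maximizing cross-validated fit
#'
#' Profiles cross-validated model quality (R2CV of the selected-`k` PLS
#' model) over a family of Box-Cox exponents and returns the winner. The
#' reference search is a dense grid over `lambdas`; a simple real-coded
#' genetic algorithm (`method = "ga"`) over the same lambda range is
#' available as an alternative optimizer. Falls back to `lambda = 1`
#' (untransformed) when no candidate beats it by more than `tol` R2CV, or
#' when every candidate model fails.
#'
#' R2CV values are unit-free (one minus a ratio of squared errors on the
#' candidate's own transformed scale), which is what makes them
#' comparable across exponents.
#'
#' @param y Positive-shifted response vector.
#' @param X Design matrix.
#' @param lambdas Candidate exponents (default `seq(-2, 3, by = 0.1)`).
#' @param tau Threshold passed to [select_k()].
#' @param k_max Maximum latent variables (default `ncol(X)`).
#' @param tol Minimum R2CV gain over `lambda = 1` required to adopt a
#'   transform (default 0.01).
#' @param method `"grid"` (reference) or `"ga"`.
#' @param ga_pop,ga_generations GA population size and generation count.
#' @param seed Seed for the GA (ignored for the grid).
#' @return Object of class `boxcox_spec`: list with `lambda`, `shift`,
#'   `objective_value` (attained R2CV), `k` (selected components),
#'   `rmsecv_curve`, `r2cv_curve`, `fallback` flag.
#' @export
boxcox_search <- function(y, X, lambdas = seq(-2, 3, by = 0.1),
                          tau = 0.02, k_max = ncol(X), tol = 0.01,
                          method = c("grid", "ga"), ga_pop = 30,
                          ga_generations = 50, seed = 1L) {
  method <- match.arg(method)
  y <- as.numeric(y); X <- as.matrix(X)
  if (any(!is.finite(y))) stop("response must be finite")
  shift <- boxcox_default_shift(y)

  eval_lambda <- function(lambda) {
    yt <- boxcox_transform(y, lambda, shift)
    if (stats::sd(yt) <= 0 || !all(is.finite(yt))) return(NULL)
    cv <- tryCatch(loo_cv(X, yt, k_max = k_max), error = function(e) NULL)
    if (is.null(cv)) return(NULL)
    k <- select_k(cv$rmsecv, tau = tau)
    list(lambda = lambda, r2cv = cv$r2cv[k], k = k,
         rmsecv_curve = cv$rmsecv, r2cv_curve = cv$r2cv)
  }

  cand <- if (method == "grid") {
    lapply(lambdas, eval_lambda)
  } else {
    ga_optimize(eval_lambda, range(lambdas), pop = ga_pop,
                generations = ga_generations, seed = seed)
  }
  cand <- Filter(Negate(is.null), cand)
  base <- eval_lambda(1)

  if (length(cand) == 0L) {
    if (is.null(base)) {
      warning("all Box-Cox candidates failed; returning lambda = 1")
      return(structure(list(lambda = 1, shift = shift,
                            objective_value = NA_real_, k = NA_integer_,
                            rmsecv_curve = NULL, r2cv_curve = NULL,
                            fallback = TRUE), class = "boxcox_spec"))
    }
    cand <- list(base)
  }
  scores <- vapply(cand, `[[`, numeric(1), "r2cv")
  best <- cand[[which.max(scores)]]
  fallback <- FALSE
  if (!is.null(base) && (best$r2cv - base$r2cv) <= tol) {
    best <- base
    fallback <- TRUE
  }
  structure(list(lambda = best$lambda, shift = shift,
                 objective_value = best$r2cv, k = best$k,
                 rmsecv_curve = best$rmsecv_curve,
                 r2cv_curve = best$r2cv_curve, fallback = fallback),
            class = "boxcox_spec")
}

## minimal real-coded GA over one parameter: tournament selection,
## blend crossover, Gaussian mutation; returns evaluated candidates
ga_optimize <- function(eval_fn, bounds, pop = 30, generations = 50,
                        seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  lo <- bounds[1]; hi <- bounds[2]
  pop_x <- stats::runif(pop, lo, hi)
  seen <- list()
  fitness <- function(x) {
    r <- eval_fn(x)
    if (!is.null(r)) seen[[length(seen) + 1L]] <<- r
    if (is.null(r)) -Inf else r$r2cv
  }
  fit <- vapply(pop_x, fitness, numeric(1))
  for (g in seq_len(generations)) {
    new_x <- numeric(pop)
    for (i in seq_len(pop)) {
      pick <- function() {
        c2 <- sample.int(pop, 2)
        c2[which.max(fit[c2])]
      }
      p1 <- pop_x[pick()]; p2 <- pop_x[pick()]
      w <- stats::runif(1)
      child <- w * p1 + (1 - w) * p2
      if (stats::runif(1) < 0.2) {
        child <- child + stats::rnorm(1, 0, 0.1 * (hi - lo))
      }
      new_x[i] <- min(max(child, lo), hi)
    }
    new_fit <- vapply(new_x, fitness, numeric(1))
    elite <- which.max(fit)
    worst <- which.min(new_fit)
    new_x[worst] <- pop_x[elite]; new_fit[worst] <- fit[elite]
    pop_x <- new_x; fit <- new_fit
  }
  seen
}
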