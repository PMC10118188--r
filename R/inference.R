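#' Wu jackknife t-tests for PLS coefficients
#'
#' Delete-one ("full cross validation") refits of the fixed-structure PLS
#' pipeline (component count `k` frozen at the full-data selection; the
#' response is supplied already on its analysis scale, so any Box-Cox
#' exponent is frozen too). The default variance is Wu's leverage-weighted
#' delete-one estimator
#' \deqn{v_r = \sum_i (1 - h_i) (\hat\beta_{(i)r} - \hat\beta_r)^2,}
#' with \eqn{h_i} the linearized PLS leverage ([pls_leverage()]); the
#' unweighted delete-one variant (`weighted = FALSE`) uses
#' \eqn{\frac{n-1}{n} \sum_i (\hat\beta_{(i)r} - \bar\beta_{(\cdot)r})^2}.
#' Each coefficient is referred to a Student-t distribution with
#' `n - DoF` degrees of freedom (DoF from [pls_dof()]).
#'
#' @param X Design matrix.
#' @param y Response on the analysis (Box-Cox) scale.
#' @param k Number of latent variables (frozen across deletions).
#' @param weighted Use Wu's leverage-weighted variance (default TRUE).
#' @return Object of class `wu_jackknife_report`: data.frame `table` with
#'   per-coefficient estimate, variance, t, p; plus `df`, `dof`, `method`,
#'   `degenerate` flag.
#' @export
wu_jackknife <- function(X, y, k, weighted = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > number of coefficients + 1")
  full <- fit_pls(X, y, k)
  h <- pls_leverage(full)
  dof <- pls_dof(full)
  Bdel <- matrix(NA_real_, p, n)
  for (i in seq_len(n)) {
    fi <- fit_pls(X[-i, , drop = FALSE], y[-i], k)
    Bdel[, i] <- fi$coefficients
  }
  b <- full$coefficients
  if (weighted) {
    v <- rowSums(sweep((Bdel - b)^2, 2, 1 - h, "*"))
    method <- "Wu full cross validation (leverage-weighted)"
  } else {
    bbar <- rowMeans(Bdel)
    v <- (n - 1) / n * rowSums((Bdel - bbar)^2)
    method <- "Wu full cross validation (unweighted)"
  }
  degenerate <- all(v < .Machine$double.eps * max(1, max(b^2)))
  tstat <- ifelse(v > 0, b / sqrt(v), ifelse(b == 0, 0, Inf))
  df <- max(n - dof, 1)
  pval <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df), 0)
  if (degenerate) pval[] <- 0       # zero residual variance: t undefined
  structure(list(
    table = data.frame(coefficient = names(b), estimate = unname(b),
                       variance = unname(v), t = unname(tstat),
                       p_value = unname(pval), stringsAsFactors = FALSE),
    df = df, dof = dof, method = method, degenerate = degenerate),
    class = "wu_jackknife_report")
}

#' Wild bootstrap (HC3) confidence intervals for a PLS model
#'
#' Fixed-design residual bootstrap for heteroscedastic errors: residuals
#' are rescaled by the HC3 factor \eqn{(1 - h_i)^{-1}} (leverage from the
#' linearized PLS hat operator), multiplied by auxiliary random signs, and
#' added back to the fitted values; the full pipeline (fixed `k`) is refit
#' on each resampled response. Percentile 95% intervals are reported for
#' every coefficient and for the predicted value of every factor-level
#' combination (cell) in the design, on the analysis (Box-Cox) scale; cell
#' predictions are also back-transformed when a transform is supplied.
#'
#' @param X Design matrix.
#' @param y Response on the analysis scale.
#' @param k Latent-variable count (frozen).
#' @param cells Named integer vector: cell label -> index of an
#'   observation row carrying that cell's regressor pattern. Defaults to
#'   one cell per distinct row of `X` (labelled by the pattern).
#' @param n_resamples Number of resamples (default 2000).
#' @param seed Integer seed (mandatory).
#' @param alpha Two-sided miss probability (default 0.05).
#' @param aux `"rademacher"` (default) or `"mammen"` auxiliary weights.
#' @param transform Optional `boxcox_spec` used to back-transform cell
#'   predictions for reporting.
#' @return Object of class `wild_bootstrap_report`: `coef_ci` data.frame
#'   (estimate, lower, upper, significant), `cell_ci` data.frame (cell,
#'   predicted, lower, upper, and back-transformed columns), `n_resamples`,
#'   `seed`, `alpha`.
#' @export
wild_bootstrap <- function(X, y, k, cells = NULL, n_resamples = 2000,
                           seed, alpha = 0.05,
                           aux = c("rademacher", "mammen"),
                           transform = NULL) {
  aux <- match.arg(aux)
  if (missing(seed)) stop("seed is required")
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  full <- fit_pls(X, y, k)
  h <- pls_leverage(full)
  capped <- h >= 1 - 1e-8
  if (any(capped)) {
    warning(sum(capped), " observation(s) with leverage ~1; weight capped")
  }
  e_scaled <- full$residuals / (1 - h)

  if (is.null(cells)) {
    key <- apply(X, 1, paste, collapse = "|")
    first <- !duplicated(key)
    cells <- stats::setNames(which(first), key[first])
  }
  cell_X <- X[cells, , drop = FALSE]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  if (aux == "rademacher") {
    S <- matrix(sample(c(-1, 1), n * n_resamples, replace = TRUE), n)
  } else {
    ## Mammen two-point distribution
    gold <- (sqrt(5) + 1) / 2
    pr <- (sqrt(5) - 1) / (2 * sqrt(5))
    S <- matrix(ifelse(stats::runif(n * n_resamples) < pr,
                       gold, 1 - gold), n)
  }

  Bco <- matrix(NA_real_, p, n_resamples,
                dimnames = list(colnames(X), NULL))
  Bcell <- matrix(NA_real_, length(cells), n_resamples)
  for (b in seq_len(n_resamples)) {
    yb <- full$fitted + e_scaled * S[, b]
    fb <- fit_pls(X, yb, k)
    Bco[, b] <- fb$coefficients
    Bcell[, b] <- predict(fb, cell_X)
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  ci_co <- t(apply(Bco, 1, stats::quantile, probs = probs, names = FALSE,
                   type = 7))
  ci_cell <- t(apply(Bcell, 1, stats::quantile, probs = probs,
                     names = FALSE, type = 7))
  pred <- predict(full, cell_X)
  cell_ci <- data.frame(cell = names(cells), predicted = pred,
                        lower = ci_cell[, 1], upper = ci_cell[, 2],
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(transform)) {
    cell_ci$predicted_original <-
      boxcox_inverse(cell_ci$predicted, transform$lambda, transform$shift)
    cell_ci$lower_original <-
      boxcox_inverse(cell_ci$lower, transform$lambda, transform$shift)
    cell_ci$upper_original <-
      boxcox_inverse(cell_ci$upper, transform$lambda, transform$shift)
  }
  structure(list(
    coef_ci = data.frame(coefficient = colnames(X),
                         estimate = unname(full$coefficients),
                         lower = ci_co[, 1], upper = ci_co[, 2],
                         significant = ci_co[, 1] > 0 | ci_co[, 2] < 0,
                         stringsAsFactors = FALSE, row.names = NULL),
    cell_ci = cell_ci, n_resamples = as.integer(n_resamples),
    seed = as.integer(seed), alpha = alpha),
    class = "wild_bootstrap_report")
}

#' Are two cell predictions significantly different?
#'
#' TRUE iff the two cells' confidence intervals are disjoint; intervals
#' touching at a single point count as intersecting (conservative).
#'
#' @param report A `wild_bootstrap_report`.
#' @param cell_a,cell_b Cell labels present in the report.
#' @return Logical.
#' @export
compare_cells <- function(report, cell_a, cell_b) {
  cc <- report$cell_ci
  ia <- match(cell_a, cc$cell); ib <- match(cell_b, cc$cell)
  if (is.na(ia) || is.na(ib)) stop("cell not present in report")
  cc$lower[ia] > cc$upper[ib] || cc$lower[ib] > cc$upper[ia]
}

#' Compact letter display from CI overlap
#'
#' Insert-and-absorb letter assignment over the pairwise
#' non-significance relation defined by CI overlap: two cells share at
#' least one letter if and only if their confidence intervals intersect.
#' Letters are indexed so that "A" is carried by the cell with the
#' largest predicted value (on the analysis scale), "B" by the next
#' distinct letter down, and so on; the alphabet extends AA, AB, ...
#' past 26 letter groups. Soundness (share-a-letter iff intervals
#' intersect) is asserted on every generated display.
#'
#' @param report A `wild_bootstrap_report` (or data.frame with `cell`,
#'   `predicted`, `lower`, `upper`).
#' @return Object of class `letter_display`: data.frame with `cell`,
#'   `predicted`, `letters` (string), ordered by decreasing prediction.
#' @export
letter_display <- function(report) {
  cc <- if (is.data.frame(report)) report else report$cell_ci
  stopifnot(nrow(cc) >= 1L)
  ord <- order(-cc$predicted)
  cc <- cc[ord, , drop = FALSE]
  m <- nrow(cc)
  overlap <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j) {
    !(cc$lower[i] > cc$upper[j] || cc$lower[j] > cc$upper[i])
  }))
  ## insert-and-absorb: columns are letter groups (logical membership)
  cols <- list(rep(TRUE, m))
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (overlap[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      ## absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(!cols[[a]] | cols[[b]]) &&
              !identical(cols[[a]], cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      ## among identical duplicates keep one
      sig <- vapply(cols, function(x) paste(as.integer(x), collapse = ""),
                    character(1))
      keep <- keep & !duplicated(sig)
      cols <- cols[keep]
    }
  }
  ## order letter groups by the largest (first) cell they contain
  firsts <- vapply(cols, function(x) which(x)[1], integer(1))
  cols <- cols[order(firsts)]
  lab <- letter_labels(length(cols))
  letters_per_cell <- vapply(seq_len(m), function(i) {
    paste(lab[vapply(cols, function(x) x[i], logical(1))], collapse = "")
  }, character(1))

  ## soundness: share a letter <=> intervals intersect
  for (i in seq_len(m)) {
    if (!nzchar(letters_per_cell[i])) {
      stop("internal error: cell without a letter")
    }
    for (j in seq_len(m)) {
      if (i == j) next
      share <- any(vapply(cols, function(x) x[i] && x[j], logical(1)))
      if (share != overlap[i, j]) {
        stop("internal error: letter display violates overlap relation")
      }
    }
  }
  out <- data.frame(cell = cc$cell, predicted = cc$predicted,
                    letters = letters_per_cell, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("letter_display", "data.frame")
  out
}

## A, B, ..., Z, AA, AB, ...
letter_labels <- function(k) {
  single <- LETTERS
  if (k <= 26) return(single[seq_len(k)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, extra)[seq_len(k)]
}
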