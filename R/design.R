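#' Dummy-coded factorial design matrix
#'
#' Converts categorical factors to 0/1 indicator regressors, deleting the
#' last level of each factor to avoid linearly dependent columns, then
#' (optionally) forms interactions as products of the retained main-effect
#' columns. Column order is main effects in factor order, then
#' interactions (pairs of factors in order, levels nested). For the
#' treatment design (4-level treatment x 2-level period) this gives
#' 3 + 1 + 3 = 7 columns; for a 12-watershed x period design,
#' 11 + 1 + 11 = 23 columns.
#'
#' @param factors Named list of factor value vectors (one entry per
#'   factor; all the same length = number of observations). Plain
#'   character vectors use order of first appearance as the level order;
#'   pass a `factor` to control level order.
#' @param with_interactions Add pairwise interaction columns (default
#'   TRUE).
#' @return Object of class `baci_design`: a numeric matrix with a
#'   `factor_map` attribute (data.frame: column, factor, level).
#' @export
build_design <- function(factors, with_interactions = TRUE) {
  stopifnot(length(factors) >= 1L, !is.null(names(factors)))
  n <- length(factors[[1]])
  cols <- list()
  fmap <- list()
  kept <- list()       # per factor: names of retained-level columns
  for (fname in names(factors)) {
    v <- factors[[fname]]
    if (length(v) != n) stop("all factors must have the same length")
    lev <- if (is.factor(v)) levels(v) else unique(as.character(v))
    v <- as.character(v)
    if (anyNA(v)) stop("factor '", fname, "' has missing levels")
    keep <- lev[-length(lev)]              # delete last level
    kept[[fname]] <- character(0)
    for (lv in keep) {
      cn <- paste0(fname, "=", lv)
      cols[[cn]] <- as.numeric(v == lv)
      fmap[[length(fmap) + 1L]] <- data.frame(
        column = cn, factor = fname, level = lv, stringsAsFactors = FALSE)
      kept[[fname]] <- c(kept[[fname]], cn)
    }
  }
  if (with_interactions && length(kept) >= 2L) {
    fn <- names(kept)
    for (i in seq_len(length(fn) - 1L)) {
      for (j in seq(i + 1L, length(fn))) {
        for (ci in kept[[fn[i]]]) {
          for (cj in kept[[fn[j]]]) {
            cn <- paste0(ci, ":", cj)
            cols[[cn]] <- cols[[ci]] * cols[[cj]]
            fmap[[length(fmap) + 1L]] <- data.frame(
              column = cn, factor = paste0(fn[i], ":", fn[j]),
              level = cn, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(cols) == 0L) stop("design has zero columns")
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  structure(X, factor_map = do.call(rbind, fmap), class = "baci_design")
}

#' Center and scale regressors and response
#'
#' Standardizes each column of `X` and the response `y` to mean 0 and
#' standard deviation 1, returning the stored means/scales so the
#' transform is invertible. A zero-variance column (or response) is an
#' error naming the offender.
#'
#' @param X Numeric matrix.
#' @param y Numeric vector (optional).
#' @return List with `X`, `y`, `x_center`, `x_scale`, `y_center`,
#'   `y_scale`.
#' @export
center_scale <- function(X, y = NULL) {
  X <- as.matrix(X)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  zero <- which(x_scale <= 0 | !is.finite(x_scale))
  if (length(zero) > 0L) {
    nm <- colnames(X)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  out <- list(X = Xs, x_center = x_center, x_scale = x_scale)
  if (!is.null(y)) {
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (y_scale <= 0 || !is.finite(y_scale)) {
      stop("zero-variance column(s): response")
    }
    out$y <- (y - y_center) / y_scale
    out$y_center <- y_center
    out$y_scale <- y_scale
  }
  out
}
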