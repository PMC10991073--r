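#' Principal component analysis on the Pearson correlation scale
#'
#' Standardizes every column to zero mean and unit variance and extracts the
#' leading `q` principal components by eigendecomposition of the Pearson
#' correlation matrix.  Component signs are fixed deterministically: each
#' weight vector is flipped so its largest-magnitude entry is positive.
#'
#' @param x Complete numeric matrix (`n x p`).
#' @param q Number of components, or `"max"` for `min(n - 1, p)`.
#' @return A list of class `pca_basis` with `center`, `scale`, `weights`
#'   (`p x q`, orthonormal columns), `eigenvalues` (all `p`, descending),
#'   `q`, and `scores` (`n x q` component scores of the fitting data).
#' @examples
#' b <- fit_pca(matrix(rnorm(200), 50, 4), q = 2)
#' crossprod(b$weights)   # identity
#' @export
fit_pca <- function(x, q = "max") {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (anyNA(x)) stop("`x` must be complete", call. = FALSE)
  qmax <- min(n - 1L, p)
  if (identical(q, "max")) q <- qmax
  q <- as.integer(q)
  if (q < 1 || q > qmax) {
    stop("`q` must be between 1 and min(n - 1, p) = ", qmax, call. = FALSE)
  }

  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  scl <- sqrt(colSums(xc^2) / (n - 1))
  if (any(scl == 0)) {
    bad <- colnames(x)[scl == 0]
    if (is.null(bad)) bad <- which(scl == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  xs <- sweep(xc, 2L, scl, "/")

  r <- crossprod(xs) / (n - 1)
  ee <- eigen(r, symmetric = TRUE)
  evals <- pmax(ee$values, 0)
  w <- ee$vectors[, seq_len(q), drop = FALSE]
  ## deterministic sign: largest-|entry| of each weight vector positive
  for (k in seq_len(q)) {
    i <- which.max(abs(w[, k]))
    if (w[i, k] < 0) w[, k] <- -w[, k]
  }
  rownames(w) <- colnames(x)

  structure(
    list(center = ctr, scale = scl, weights = w,
         eigenvalues = evals, q = q, scores = xs %*% w),
    class = "pca_basis"
  )
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("PCA basis: ", length(x$center), " variables, ", x$q,
      " components\n", sep = "")
  ev <- x$eigenvalues[seq_len(min(x$q, 8L))]
  cat("  leading eigenvalues: ", paste(sprintf("%.3f", ev), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project new rows onto a fitted component basis
#'
#' Applies the stored centring and scaling constants, then multiplies by the
#' weight matrix.  Projecting the fitting data reproduces the fitted scores.
#'
#' @param basis A [fit_pca()] result.
#' @param x_new Complete matrix with the same `p` columns as the fit.
#' @return `n_new x q` matrix of component scores.
#' @export
project <- function(basis, x_new) {
  stopifnot(inherits(basis, "pca_basis"))
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != length(basis$center)) {
    stop("`x_new` must have ", length(basis$center), " columns",
         call. = FALSE)
  }
  xs <- sweep(sweep(x_new, 2L, basis$center), 2L, basis$scale, "/")
  xs %*% basis$weights
}
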