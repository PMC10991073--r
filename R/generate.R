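#' Generate fully observed data from a latent design
#'
#' Draws latent factor scores from a multivariate normal with the design's
#' latent correlation matrix, adds uncorrelated normal measurement error with
#' variance \eqn{1 - \lambda^2}, rescales every column to (approximately)
#' mean 5 and variance 6.5 using sample moments, and finally coarsens the
#' auxiliary columns (roles `M` and `A`) to `n_cat` ordinal levels.  The four
#' imputation-target columns (role `T`) always stay continuous.
#'
#' @param design A [`build_design()`] object.
#' @param n Number of rows (500 in both studies).
#' @param n_cat Coarseness of the auxiliary columns: `Inf` (continuous), 7,
#'   5, 3, or 2 equal-probability categories.
#' @param seed Optional integer seed; the draw is deterministic given the
#'   seed.
#'
#' @return An object of class `sim_data`: a list with `X` (the `n x p`
#'   matrix, columns `x1..xp`, coarsened where applicable), `X_cont` (the
#'   matrix before coarsening; the missingness mechanism always operates on
#'   this), `roles`, `n_cat`, and `design`.
#'
#' @examples
#' d <- build_design(pn = 0, study = 1)
#' sim <- generate_data(d, n = 500, n_cat = Inf, seed = 1)
#' dim(sim$X)          # 500 x 56
#' round(mean(sim$X[, 1]), 2)
#' @export
generate_data <- function(design, n = 500, n_cat = Inf, seed = NULL) {
  stopifnot(inherits(design, "latent_design"))
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (!n_cat %in% c(Inf, 7, 5, 3, 2)) {
    stop("`n_cat` must be one of Inf, 7, 5, 3, 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  psi_chol <- tryCatch(chol(design$psi),
                       error = function(e)
                         stop("latent correlation matrix is not positive definite",
                              call. = FALSE))
  p <- sum(design$items_per_factor)
  lambda <- make_loadings(design)

  f <- matrix(stats::rnorm(n * design$n_factors), n) %*% psi_chol
  e <- matrix(stats::rnorm(n * p, sd = sqrt(design$error_var)), n, p)
  x <- f %*% t(lambda) + e

  ## rescale with sample moments to mean 5 / variance 6.5
  x <- scale(x)
  x <- x * sqrt(design$target_var) + design$target_mean
  attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  colnames(x) <- paste0("x", seq_len(p))

  x_cont <- x
  if (is.finite(n_cat)) {
    aux <- which(design$roles != "T")
    for (j in aux) x[, j] <- discretize_column(x[, j], n_cat)
  }

  structure(
    list(X = x, X_cont = x_cont, roles = design$roles,
         n_cat = n_cat, design = design),
    class = "sim_data"
  )
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Simulated data: ", nrow(x$X), " x ", ncol(x$X),
      " (roles: ", sum(x$roles == "T"), " T, ", sum(x$roles == "M"),
      " M, ", sum(x$roles == "A"), " A; n_cat = ", x$n_cat, ")\n", sep = "")
  invisible(x)
}

#' Coarsen a continuous column to ordinal categories
#'
#' Equal-probability (sample-quantile) cuts into `n_cat` categories labelled
#' `1..n_cat`, so category frequencies are approximately balanced.
#' `n_cat = Inf` is the identity.
#'
#' @param values Numeric vector.
#' @param n_cat Number of categories (`Inf`, 7, 5, 3, or 2).
#' @return Integer-valued vector of levels `1..n_cat` (or `values` unchanged
#'   when `n_cat = Inf`).
#' @export
discretize_column <- function(values, n_cat) {
  if (!n_cat %in% c(Inf, 7, 5, 3, 2)) {
    stop("`n_cat` must be one of Inf, 7, 5, 3, 2", call. = FALSE)
  }
  if (!is.finite(n_cat)) return(values)
  if (length(unique(values)) <= n_cat) {
    stop("fewer distinct values than categories requested", call. = FALSE)
  }
  brk <- stats::quantile(values, probs = seq(0, 1, length.out = n_cat + 1),
                         names = FALSE)
  brk <- unique(brk)
  as.numeric(cut(values, breaks = brk, labels = FALSE, include.lowest = TRUE))
}
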