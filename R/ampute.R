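#' Calibrate the intercept of the missingness logit model
#'
#' Finds the intercept \eqn{\beta_0} such that the mean of
#' `plogis(beta0 + eta)` equals `target_prop`, by bracketed root finding on
#' `[-20, 20]` to a tolerance of 1e-6 on the proportion.  The linear
#' predictor `eta` is typically the row sum of the missingness predictors
#' (all slopes equal to 1).
#'
#' @param eta Numeric vector, the linear predictor without intercept.
#' @param target_prop Desired proportion of missing values, in (0, 1).
#' @return The calibrated scalar intercept.
#' @examples
#' solve_mar_intercept(rep(0, 100), 0.3)  # logit(0.3) = -0.8473
#' @export
solve_mar_intercept <- function(eta, target_prop = 0.3) {
  if (any(!is.finite(eta))) stop("`eta` must be finite", call. = FALSE)
  if (target_prop <= 0 || target_prop >= 1) {
    stop("`target_prop` must be in (0, 1)", call. = FALSE)
  }
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target_prop
  lo <- -20; hi <- 20
  ## widen the bracket if eta is far off-centre
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Impose calibrated right-tail MAR missingness
#'
#' Blanks cells in the four target (`T`) columns according to a logistic
#' missingness model whose linear predictor is the weighted sum of the
#' *continuous* `M` columns with all slopes fixed to 1 (the auxiliary
#' coarsening never weakens the mechanism).  Following standard amputation
#' practice, the weighted sum score is standardized to unit variance before
#' the probability curve is applied, so that the strength of the mechanism
#' does not depend on the measurement scale of the predictors.  For each
#' target column independently, the
#' intercept is calibrated with [solve_mar_intercept()] so that the expected
#' missingness proportion equals `target_prop`, an indicator is drawn from
#' the induced Bernoulli probabilities, and flagged cells are set to `NA`.
#' Positive slopes align missingness with the upper tail of the predictor
#' score (right-tail MAR).
#'
#' @param sim A [`generate_data()`] object (or compatible list with `X`,
#'   `X_cont`, `roles`).
#' @param target_prop Proportion of missing cells per target column (0.3 in
#'   the studies).
#' @param slopes Slopes on the `M` columns; scalar or vector of length
#'   `|M|`.  All zeros gives MCAR at `target_prop`.
#' @param seed Optional integer seed.
#'
#' @return An object of class `incomplete_data`: list with `data` (matrix
#'   with `NA` cells), `response` (0/1 matrix, 1 = missing), `roles`,
#'   `spec` (target proportion, slopes, per-column intercepts), and the
#'   originating `sim` (for truth bookkeeping in simulations).
#' @export
impose_mar <- function(sim, target_prop = 0.3, slopes = 1, seed = NULL) {
  stopifnot(is.list(sim), !is.null(sim$X), !is.null(sim$roles))
  x_cont <- if (!is.null(sim$X_cont)) sim$X_cont else sim$X
  m_cols <- which(sim$roles == "M")
  t_cols <- which(sim$roles == "T")
  if (anyNA(x_cont[, m_cols])) {
    stop("missingness predictors (M columns) must be complete", call. = FALSE)
  }
  slopes <- rep_len(slopes, length(m_cols))
  if (!is.null(seed)) set.seed(seed)

  eta <- as.vector(x_cont[, m_cols, drop = FALSE] %*% slopes)
  ## scale-free mechanism: standardize the weighted sum score (a constant
  ## score, e.g. all slopes 0, is left as is and yields MCAR)
  if (stats::sd(eta) > 0) eta <- (eta - mean(eta)) / stats::sd(eta)
  x <- sim$X
  delta <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  b0 <- numeric(length(t_cols))
  for (i in seq_along(t_cols)) {
    b0[i] <- solve_mar_intercept(eta, target_prop)
    pr <- stats::plogis(b0[i] + eta)
    d <- stats::rbinom(length(pr), 1L, pr)
    delta[, t_cols[i]] <- d
    x[d == 1L, t_cols[i]] <- NA_real_
  }

  structure(
    list(data = x, response = delta, roles = sim$roles,
         spec = list(target_prop = target_prop, slopes = slopes,
                     intercepts = b0, mechanism = "right-tail MAR"),
         sim = sim),
    class = "incomplete_data"
  )
}

#' @export
print.incomplete_data <- function(x, ...) {
  fr <- colMeans(x$response[, x$roles == "T", drop = FALSE])
  cat("Incomplete data: ", nrow(x$data), " x ", ncol(x$data), "\n", sep = "")
  cat("  per-target missing fraction: ",
      paste(sprintf("%.3f", fr), collapse = ", "), "\n", sep = "")
  invisible(x)
}

## coerce a bare matrix with NAs into the incomplete_data shape used by the
## imputation front-ends (roles unknown -> all "T"-like handling is bypassed)
as_incomplete <- function(x) {
  if (inherits(x, "incomplete_data")) return(x)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  delta <- matrix(as.integer(is.na(x)), nrow(x), ncol(x),
                  dimnames = dimnames(x))
  structure(list(data = x, response = delta, roles = NULL, spec = NULL),
            class = "incomplete_data")
}
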