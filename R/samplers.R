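#' Bayesian normal linear imputation draw
#'
#' One draw from the posterior predictive distribution of a normal linear
#' model under the standard noninformative prior: the residual variance is
#' drawn as \eqn{\sigma^{2*} = \mathrm{SSR}/\chi^2_{\nu}} with
#' \eqn{\nu = n_{obs} - q} (floored at 1), the coefficients from
#' \eqn{N(\hat\beta, \sigma^{2*}(X'X + \kappa I)^{-1})}, and the
#' imputations as the linear predictions for the missing rows plus
#' \eqn{N(0, \sigma^{2*})} noise.  A small ridge \eqn{\kappa} stabilizes the
#' cross-product matrix when predictors are (nearly) collinear.
#'
#' The caller supplies design matrices that already include an intercept
#' column.  Draws consume the global R random number stream.
#'
#' @param y_obs Observed outcome values.
#' @param x_obs Design matrix for the observed rows.
#' @param x_mis Design matrix for the rows to impute.
#' @param ridge Ridge stabilization constant added to the diagonal of
#'   `X'X` (default `1e-5`).
#' @return Numeric vector of `nrow(x_mis)` imputed values.
#' @export
draw_bayes_norm <- function(y_obs, x_obs, x_mis, ridge = 1e-5) {
  par <- bayes_lm_draw(y_obs, x_obs, ridge)
  as.vector(x_mis %*% par$beta_dot) +
    stats::rnorm(nrow(x_mis), sd = sqrt(par$sigma2))
}

## shared parameter draw for the normal linear model
bayes_lm_draw <- function(y_obs, x_obs, ridge = 1e-5) {
  x_obs <- as.matrix(x_obs)
  n_obs <- length(y_obs)
  q <- ncol(x_obs)
  if (nrow(x_obs) != n_obs) stop("row mismatch", call. = FALSE)
  xtx <- crossprod(x_obs)
  if (ridge > 0) xtx <- xtx + diag(ridge, q)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular cross-product matrix; increase `ridge`", call. = FALSE)
  }
  v <- chol2inv(ch)
  beta_hat <- v %*% crossprod(x_obs, y_obs)
  resid <- y_obs - as.vector(x_obs %*% beta_hat)
  df <- max(n_obs - q, 1L)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  beta_dot <- beta_hat +
    sqrt(sigma2) * t(chol((v + t(v)) / 2)) %*% stats::rnorm(q)
  list(beta_hat = beta_hat, beta_dot = beta_dot, sigma2 = sigma2)
}

#' Predictive mean matching imputation draw
#'
#' Draws model parameters exactly as [draw_bayes_norm()], computes predicted
#' values for the observed rows from the least-squares estimate and for the
#' missing rows from the coefficient draw (type-1 matching), and for each
#' missing row returns the observed outcome of one donor sampled uniformly
#' from the `donors` observed rows with smallest absolute predictive
#' distance.  Imputations are therefore always members of the observed
#' support.
#'
#' @inheritParams draw_bayes_norm
#' @param donors Size of the donor pool (default 5).
#' @return Numeric vector of `nrow(x_mis)` imputed values drawn from
#'   `y_obs`.
#' @export
draw_pmm <- function(y_obs, x_obs, x_mis, ridge = 1e-5, donors = 5L) {
  if (donors < 1) stop("`donors` must be at least 1", call. = FALSE)
  if (donors > length(y_obs)) {
    stop("`donors` exceeds the number of observed values", call. = FALSE)
  }
  par <- bayes_lm_draw(y_obs, x_obs, ridge)
  yhat_obs <- as.vector(as.matrix(x_obs) %*% par$beta_hat)
  yhat_mis <- as.vector(as.matrix(x_mis) %*% par$beta_dot)
  n_mis <- length(yhat_mis)
  out <- numeric(n_mis)
  for (i in seq_len(n_mis)) {
    d <- abs(yhat_obs - yhat_mis[i])
    pool <- order(d)[seq_len(donors)]
    out[i] <- y_obs[pool[sample.int(donors, 1L)]]
  }
  out
}
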