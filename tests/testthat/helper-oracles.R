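# Independent oracles and small fixtures used across the suite.

# Brute-force posterior draw for the normal linear model, written against
# the formulas directly (solve() instead of Cholesky inverses).  Consumes
# the RNG stream in the same order as draw_bayes_norm.
oracle_bayes_norm <- function(y_obs, x_obs, x_mis, ridge = 0) {
  x_obs <- as.matrix(x_obs); x_mis <- as.matrix(x_mis)
  q <- ncol(x_obs)
  xtx <- t(x_obs) %*% x_obs + diag(ridge, q)
  v <- solve(xtx)
  beta_hat <- v %*% t(x_obs) %*% y_obs
  ssr <- sum((y_obs - x_obs %*% beta_hat)^2)
  df <- max(length(y_obs) - q, 1)
  sigma2 <- ssr / rchisq(1, df)
  beta_dot <- beta_hat + sqrt(sigma2) * t(chol((v + t(v)) / 2)) %*% rnorm(q)
  as.vector(x_mis %*% beta_dot) + rnorm(nrow(x_mis)) * sqrt(sigma2)
}

# Rubin's rules evaluated naively for one estimand.
oracle_rubin <- function(qs, ses, n) {
  m <- length(qs)
  qbar <- sum(qs) / m
  ubar <- sum(ses^2) / m
  b <- sum((qs - qbar)^2) / (m - 1)
  t_var <- ubar + (1 + 1 / m) * b
  df_com <- n - 1
  lambda <- (1 + 1 / m) * b / t_var
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  df <- if (b > 0) {
    df_old <- (m - 1) / lambda^2
    df_old * df_obs / (df_old + df_obs)
  } else df_obs
  half <- qt(0.975, df) * sqrt(t_var)
  c(qbar = qbar, ubar = ubar, b = b, t = t_var, df = df,
    lo = qbar - half, hi = qbar + half)
}

# Fabricate an aligned list of moment-estimate tables for pool_rubin,
# all on the identity scale.
fake_estimates <- function(qmat, semat, n = 100) {
  k <- nrow(qmat)
  lapply(seq_len(ncol(qmat)), function(i) {
    out <- data.frame(
      estimand = paste0("mean(v", seq_len(k), ")"),
      type = "mean", estimate = qmat[, i], q = qmat[, i],
      se = semat[, i], transform = "identity", n = n,
      stringsAsFactors = FALSE)
    class(out) <- c("param_estimates", "data.frame")
    out
  })
}

# Small incomplete multivariate-normal fixture with MAR missingness on the
# first column, for engine-level tests.
toy_incomplete <- function(n = 120, p = 6, prop = 0.25, seed = 1) {
  set.seed(seed)
  r <- 0.5^abs(outer(seq_len(p), seq_len(p), "-"))
  x <- matrix(rnorm(n * p), n) %*% chol(r)
  colnames(x) <- paste0("x", seq_len(p))
  pr <- plogis(solve_mar_intercept(x[, 2], prop) + x[, 2])
  x[rbinom(n, 1, pr) == 1, 1] <- NA
  x
}

study1_targets <- paste0("x", 1:4)
study1_mar <- paste0("x", 5:8)
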