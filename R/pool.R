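#' Moment estimates of the analysis columns with pooling-scale SEs
#'
#' Estimates, from one complete data set, the means, variances, covariances
#' and correlations of the analysis columns, together with the standard
#' error of each estimate on the scale used for pooling:
#' means on the identity scale (`s/sqrt(n)`), variances on the log scale
#' (`sqrt(2/(n-1))`), covariances on the identity scale
#' (`sqrt((s2x*s2y + sxy^2)/(n-1))`), and correlations on the Fisher-z scale
#' (`1/sqrt(n-3)`).
#'
#' @param x Complete numeric matrix.
#' @param targets Names of the analysis columns (4 in the studies, giving
#'   4 means, 4 variances, 6 covariances, 6 correlations).
#' @return A data frame of class `param_estimates` with columns `estimand`
#'   (e.g. `"cor(x1,x2)"`), `type`, `estimate` (natural scale), `q`
#'   (pooling scale), `se` (pooling scale), `transform`, `n`.
#' @export
estimate_moments <- function(x, targets) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("`x` must be complete", call. = FALSE)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 rows", call. = FALSE)
  if (!all(targets %in% colnames(x))) stop("unknown target(s)", call. = FALSE)
  y <- x[, targets, drop = FALSE]
  s2 <- apply(y, 2L, stats::var)
  if (any(s2 == 0)) stop("zero-variance target(s)", call. = FALSE)

  rows <- list()
  add <- function(estimand, type, estimate, q, se, transform) {
    rows[[length(rows) + 1L]] <<- data.frame(
      estimand = estimand, type = type, estimate = estimate, q = q,
      se = se, transform = transform, n = n, stringsAsFactors = FALSE)
  }
  for (v in targets) {
    add(paste0("mean(", v, ")"), "mean", mean(y[, v]), mean(y[, v]),
        sqrt(s2[[v]] / n), "identity")
  }
  for (v in targets) {
    add(paste0("var(", v, ")"), "variance", s2[[v]], log(s2[[v]]),
        sqrt(2 / (n - 1)), "log")
  }
  k <- length(targets)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- targets[i]; b <- targets[j]
      sab <- stats::cov(y[, a], y[, b])
      add(paste0("cov(", a, ",", b, ")"), "covariance", sab, sab,
          sqrt((s2[[a]] * s2[[b]] + sab^2) / (n - 1)), "identity")
      r <- stats::cor(y[, a], y[, b])
      add(paste0("cor(", a, ",", b, ")"), "correlation", r, atanh(r),
          1 / sqrt(n - 3), "fisher-z")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("param_estimates", "data.frame")
  out
}

back_transform <- function(q, transform) {
  switch(transform, identity = q, log = exp(q), `fisher-z` = tanh(q),
         stop("unknown transform", call. = FALSE))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' On the pooling scale of each estimand: the pooled point estimate is the
#' mean of the `m` per-imputation estimates, the within-imputation variance
#' is the mean squared SE, the between-imputation variance is the sample
#' variance of the estimates, and the total variance is
#' `t = ubar + (1 + 1/m) b`.  Degrees of freedom follow the Barnard-Rubin
#' small-sample formula with complete-data df `n - 1`; 95% intervals are
#' formed on the pooling scale and back-transformed.
#'
#' @param per_imp List of `m >= 2` [estimate_moments()] tables, one per
#'   imputed data set, with identical estimand layout.
#' @param conf_level Confidence level (fixed at 0.95 in the studies).
#' @return A data frame of class `mi_pooled` with columns `estimand`,
#'   `type`, `estimate` (back-transformed pooled estimate), `qbar`, `ubar`,
#'   `b`, `t`, `df`, `ci_lower`, `ci_upper`, `m`, `transform`, `n`.
#' @export
pool_rubin <- function(per_imp, conf_level = 0.95) {
  m <- length(per_imp)
  if (m < 2) stop("need m >= 2 imputations to pool", call. = FALSE)
  key <- per_imp[[1]]$estimand
  for (tab in per_imp) {
    if (!identical(tab$estimand, key) ||
        !identical(tab$transform, per_imp[[1]]$transform)) {
      stop("imputation estimate tables are not aligned", call. = FALSE)
    }
  }
  qmat <- vapply(per_imp, function(tab) tab$q, numeric(length(key)))
  semat <- vapply(per_imp, function(tab) tab$se, numeric(length(key)))
  qmat <- matrix(qmat, nrow = length(key))
  semat <- matrix(semat, nrow = length(key))

  qbar <- rowMeans(qmat)
  ubar <- rowMeans(semat^2)
  b <- apply(qmat, 1L, stats::var)
  t_var <- ubar + (1 + 1 / m) * b

  n <- per_imp[[1]]$n
  df_com <- n - 1
  lambda <- (1 + 1 / m) * b / t_var
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  df <- ifelse(b > 0,
               {
                 df_old <- (m - 1) / pmax(lambda, .Machine$double.eps)^2
                 df_old * df_obs / (df_old + df_obs)
               },
               df_obs)

  alpha <- 1 - conf_level
  half <- stats::qt(1 - alpha / 2, df) * sqrt(t_var)
  tr <- per_imp[[1]]$transform
  lo <- mapply(back_transform, qbar - half, tr)
  hi <- mapply(back_transform, qbar + half, tr)
  est <- mapply(back_transform, qbar, tr)

  out <- data.frame(
    estimand = key, type = per_imp[[1]]$type, estimate = est,
    qbar = qbar, ubar = ubar, b = b, t = t_var, df = df,
    ci_lower = lo, ci_upper = hi, m = m, transform = tr, n = n,
    stringsAsFactors = FALSE)
  class(out) <- c("mi_pooled", "data.frame")
  out
}

#' Pool the moment estimates of an imputation result
#'
#' Convenience wrapper: estimates the moments of the analysis columns on
#' each completed data set of an `mi_result` and pools them by Rubin's
#' rules.
#'
#' @param result An `mi_result`.
#' @param targets Analysis column names.
#' @param conf_level Confidence level.
#' @return An `mi_pooled` table.
#' @export
pool_moments <- function(result, targets, conf_level = 0.95) {
  stopifnot(inherits(result, "mi_result"))
  pool_rubin(lapply(result$completed, estimate_moments, targets = targets),
             conf_level = conf_level)
}

#' Score pooled estimates against the full-data truth
#'
#' Computes the three Monte Carlo outcome measures over `S` replications.
#' The truth for each estimand is the mean of the full-data estimates
#' across replications.  Absolute percent relative bias is
#' `|mean(est) - truth| / |truth| * 100` (flagged above 10); confidence
#' interval width is the mean of `upper - lower`; coverage is the fraction
#' of intervals containing the truth (flagged below 0.9).  When the truth
#' is exactly zero the relative bias is undefined and the absolute bias is
#' reported instead, with a flag.
#'
#' @param pooled List over replications of [pool_rubin()] /
#'   [pool_moments()] tables with identical estimand layout.
#' @param full List over replications of [estimate_moments()] tables
#'   computed on the corresponding fully observed data.
#' @return A data frame of class `metric_table` with columns `estimand`,
#'   `type`, `truth`, `est_mean`, `prb`, `abs_bias`, `ciw`, `cic`, `S`,
#'   `prb_flag`, `cic_flag`, `truth_zero`.
#' @export
evaluate_metrics <- function(pooled, full) {
  s <- length(pooled)
  if (s < 1 || length(full) != s) {
    stop("`pooled` and `full` must be non-empty and aligned", call. = FALSE)
  }
  key <- pooled[[1]]$estimand
  est <- vapply(pooled, function(tab) tab$estimate, numeric(length(key)))
  lo <- vapply(pooled, function(tab) tab$ci_lower, numeric(length(key)))
  hi <- vapply(pooled, function(tab) tab$ci_upper, numeric(length(key)))
  est <- matrix(est, nrow = length(key))
  lo <- matrix(lo, nrow = length(key))
  hi <- matrix(hi, nrow = length(key))
  fe <- matrix(vapply(full, function(tab) tab$estimate,
                      numeric(length(key))), nrow = length(key))

  truth <- rowMeans(fe)
  est_mean <- rowMeans(est)
  abs_bias <- abs(est_mean - truth)
  prb <- ifelse(truth != 0, abs_bias / abs(truth) * 100, NA_real_)
  ciw <- rowMeans(hi - lo)
  cic <- rowMeans(lo <= truth & truth <= hi)

  out <- data.frame(
    estimand = key, type = pooled[[1]]$type, truth = truth,
    est_mean = est_mean, prb = prb, abs_bias = abs_bias,
    ciw = ciw, cic = cic, S = s,
    prb_flag = !is.na(prb) & prb > 10,
    cic_flag = cic < 0.9,
    truth_zero = truth == 0,
    stringsAsFactors = FALSE)
  class(out) <- c("metric_table", "data.frame")
  out
}
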