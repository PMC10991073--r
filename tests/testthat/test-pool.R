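test_that("moment estimates carry hand-computed values and pooling SEs", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(1.2, 1.9, 3.4, 3.9, 5.1))
  est <- estimate_moments(x, c("a", "b"))
  expect_equal(nrow(est), 2 + 2 + 1 + 1)
  r <- cor(x[, 1], x[, 2])
  row <- est[est$estimand == "cor(a,b)", ]
  expect_equal(row$estimate, r)
  expect_equal(row$q, atanh(r))
  expect_equal(row$se, 1 / sqrt(2))      # 1/sqrt(n - 3), n = 5
  row_m <- est[est$estimand == "mean(a)", ]
  expect_equal(row_m$estimate, 3)
  expect_equal(row_m$se, sd(x[, 1]) / sqrt(5))
  row_v <- est[est$estimand == "var(b)", ]
  expect_equal(row_v$q, log(var(x[, 2])))
  expect_equal(row_v$se, sqrt(2 / 4))
  row_c <- est[est$estimand == "cov(a,b)", ]
  s2a <- var(x[, 1]); s2b <- var(x[, 2]); sab <- cov(x[, 1], x[, 2])
  expect_equal(row_c$se, sqrt((s2a * s2b + sab^2) / 4))
})

test_that("moment estimates respect shift invariance and input checks", {
  set.seed(1)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("x", 1:4)))
  e1 <- estimate_moments(x, paste0("x", 1:4))
  e2 <- estimate_moments(x + 10, paste0("x", 1:4))
  means <- e1$type == "mean"
  expect_equal(e2$estimate[means], e1$estimate[means] + 10)
  expect_equal(e2$estimate[!means], e1$estimate[!means])
  expect_equal(sum(e1$type == "correlation"), 6)   # only distinct pairs
  expect_error(estimate_moments(cbind(x, k = rep(1, 20)),
                                c("x1", "k")), "zero-variance")
})

test_that("rubin pooling equals the brute-force formulas", {
  # worked example: estimates 1.0/1.2/1.4 with se^2 = 0.04 each
  tabs <- fake_estimates(qmat = matrix(c(1.0, 1.2, 1.4), 1),
                         semat = matrix(0.2, 1, 3), n = 100)
  p <- pool_rubin(tabs)
  expect_equal(p$qbar, 1.2)
  expect_equal(p$b, 0.04)
  expect_equal(p$t, 0.04 + (1 + 1 / 3) * 0.04)
  expect_equal(p$t, 0.09333333, tolerance = 1e-6)
  # 1000 random estimands at once against the naive implementation
  set.seed(2)
  k <- 1000; m <- 5
  qmat <- matrix(rnorm(k * m), k)
  semat <- matrix(runif(k * m, 0.05, 0.5), k)
  pooled <- pool_rubin(fake_estimates(qmat, semat, n = 73))
  for (i in seq_len(k)) {
    o <- oracle_rubin(qmat[i, ], semat[i, ], n = 73)
    expect_equal(pooled$qbar[i], o[["qbar"]], tolerance = 1e-12)
    expect_equal(pooled$ubar[i], o[["ubar"]], tolerance = 1e-12)
    expect_equal(pooled$b[i], o[["b"]], tolerance = 1e-12)
    expect_equal(pooled$t[i], o[["t"]], tolerance = 1e-12)
    expect_equal(pooled$df[i], o[["df"]], tolerance = 1e-9)
    expect_equal(pooled$ci_lower[i], o[["lo"]], tolerance = 1e-9)
    expect_equal(pooled$ci_upper[i], o[["hi"]], tolerance = 1e-9)
  }
  expect_true(all(pooled$t >= pooled$ubar))
})

test_that("pooling handles degenerate and invalid inputs", {
  tabs <- fake_estimates(matrix(1.5, 1, 4), matrix(0.3, 1, 4), n = 50)
  p <- pool_rubin(tabs)        # identical estimates: b = 0, t = ubar
  expect_equal(p$b, 0)
  expect_equal(p$t, p$ubar)
  single <- fake_estimates(matrix(1, 1, 1), matrix(0.1, 1, 1))
  expect_error(pool_rubin(single), "m >= 2")
})

test_that("back-transformed correlation intervals stay inside (-1, 1)", {
  x <- toy_incomplete(n = 150, p = 5, seed = 3)
  res <- impute_mi_or(x, analysis_cols = c("x1", "x2"),
                      mar_predictor_cols = c("x3", "x4"), m = 5,
                      maxit = 5, seed = 4)
  p <- pool_moments(res, c("x1", "x2"))
  corr <- p[p$type == "correlation", ]
  expect_true(all(corr$ci_lower > -1 & corr$ci_upper < 1))
  expect_true(all(p$ci_lower < p$ci_upper))
  vr <- p[p$type == "variance", ]
  expect_true(all(vr$ci_lower > 0))
})

test_that("metric evaluation implements the bias, width, coverage formulas", {
  mk_pooled <- function(est, lo, hi) {
    data.frame(estimand = "mean(x1)", type = "mean", estimate = est,
               qbar = est, ubar = 1, b = 0, t = 1, df = 10,
               ci_lower = lo, ci_upper = hi, m = 5,
               transform = "identity", n = 100)
  }
  mk_full <- function(v) data.frame(estimand = "mean(x1)", type = "mean",
                                    estimate = v, q = v, se = 1,
                                    transform = "identity", n = 100)
  # perfect recovery
  pooled <- replicate(10, mk_pooled(0.5, 0.4, 0.6), simplify = FALSE)
  full <- replicate(10, mk_full(0.5), simplify = FALSE)
  met <- evaluate_metrics(pooled, full)
  expect_equal(met$prb, 0)
  expect_equal(met$cic, 1)
  expect_equal(met$ciw, 0.2)
  # boundary: truth 0.5, mean estimate 0.55 -> PRB exactly 10
  met2 <- evaluate_metrics(replicate(4, mk_pooled(0.55, 0, 1),
                                     simplify = FALSE),
                           replicate(4, mk_full(0.5), simplify = FALSE))
  expect_equal(met2$prb, 10)
  # flags trip strictly above the threshold
  met2b <- evaluate_metrics(replicate(4, mk_pooled(4.5, 0, 9),
                                      simplify = FALSE),
                            replicate(4, mk_full(4), simplify = FALSE))
  expect_equal(met2b$prb, 12.5)
  expect_true(met2b$prb_flag)
  # coverage counting: 95 of 100 intervals cover
  pooled3 <- c(replicate(95, mk_pooled(0.5, 0.4, 0.6), simplify = FALSE),
               replicate(5, mk_pooled(0.8, 0.7, 0.75), simplify = FALSE))
  met3 <- evaluate_metrics(pooled3, replicate(100, mk_full(0.5),
                                              simplify = FALSE))
  expect_equal(met3$cic, 0.95)
  # zero truth: PRB undefined, absolute bias reported with a flag
  met4 <- evaluate_metrics(replicate(3, mk_pooled(0.1, -1, 1),
                                     simplify = FALSE),
                           replicate(3, mk_full(0), simplify = FALSE))
  expect_true(is.na(met4$prb))
  expect_true(met4$truth_zero)
  expect_equal(met4$abs_bias, 0.1)
})

test_that("relative bias of means is invariant to multiplicative rescaling", {
  set.seed(5)
  mk <- function(scl) {
    x <- matrix(rnorm(200, mean = 3), 50, 4,
                dimnames = list(NULL, paste0("x", 1:4))) * scl
    estimate_moments(x, paste0("x", 1:4))
  }
  full1 <- replicate(20, mk(1), simplify = FALSE)
  # synthetic pooled tables derived from the same estimates, then rescaled
  to_pooled <- function(tab, scl) {
    data.frame(estimand = tab$estimand, type = tab$type,
               estimate = tab$estimate * scl, qbar = tab$q, ubar = 1,
               b = 0, t = 1, df = 10, ci_lower = tab$estimate * scl - 1,
               ci_upper = tab$estimate * scl + 1, m = 5,
               transform = tab$transform, n = tab$n)
  }
  scale_full <- function(tab, scl) { tab$estimate <- tab$estimate * scl; tab }
  m1 <- evaluate_metrics(lapply(full1, to_pooled, scl = 1), full1)
  m2 <- evaluate_metrics(lapply(full1, to_pooled, scl = 3),
                         lapply(full1, scale_full, scl = 3))
  means <- m1$type == "mean"
  expect_equal(m1$prb[means], m2$prb[means], tolerance = 1e-10)
})
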