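test_that("maximum component counts resolve per strategy", {
  sim <- generate_data(build_design(0), n = 500, n_cat = Inf, seed = 1)
  inc <- impose_mar(sim, 0.3)
  # aux: p - 4 = 52; all: p = 56; vbv: p - 1 = 55 (bounded by n - 1)
  expect_error(impute_mi_pcr_aux(inc, study1_targets, npc = 53, m = 2,
                                 maxit = 1), "between 1 and 52")
  expect_error(impute_mi_pcr_all(inc, npc = 57, m = 2), "between 1 and 56")
  expect_error(impute_mi_pcr_vbv(inc, npc = 56, m = 2, maxit = 1),
               "between 1 and 55")
  expect_equal(mipcr:::resolve_npc("max", 52, ""), 52L)
  expect_equal(mipcr:::resolve_npc("max", 55, ""), 55L)
})

test_that("pretreat single imputation completes data without touching observations", {
  x <- toy_incomplete(n = 150, p = 6, seed = 2)
  filled <- single_impute_pretreat(x, threshold = 0.3, maxit = 5, seed = 3)
  expect_false(anyNA(filled))
  obs <- !is.na(x)
  expect_identical(filled[obs], x[obs])
  # complete input is returned unchanged
  expect_identical(single_impute_pretreat(filled), filled)
  # impossible threshold: every target falls back to intercept-only
  expect_message(single_impute_pretreat(x, threshold = 1, maxit = 2,
                                        seed = 4),
                 "intercept-only")
})

test_that("aux strategy keeps raw analysis columns and fixed auxiliary scores", {
  sim <- generate_data(build_design(0), n = 300, n_cat = Inf, seed = 5)
  inc <- impose_mar(sim, 0.3)
  res <- impute_mi_pcr_aux(inc, study1_targets, npc = 8, m = 2, maxit = 3,
                           seed = 6)
  expect_length(res$completed, 2)
  expect_false(anyNA(res$completed[[1]]))
  obs <- !is.na(inc$data)
  expect_identical(res$completed[[1]][obs], inc$data[obs])
  # auxiliary columns are complete, so the pretreat is a no-op and the
  # auxiliaries are returned untouched in every imputation
  aux <- setdiff(colnames(inc$data), study1_targets)
  expect_identical(res$completed[[1]][, aux], inc$data[, aux])
})

test_that("all-variables strategy imputes in a single sweep", {
  sim <- generate_data(build_design(0), n = 300, n_cat = Inf, seed = 7)
  inc <- impose_mar(sim, 0.3)
  res <- impute_mi_pcr_all(inc, npc = 8, m = 3, seed = 8)
  expect_equal(res$maxit, 1L)
  expect_false(anyNA(res$completed[[1]]))
  # fresh posterior draws per imputation: completed sets differ in the
  # imputed cells but agree on the observed ones
  mis <- is.na(inc$data)
  expect_false(identical(res$completed[[1]][mis], res$completed[[2]][mis]))
  expect_identical(res$completed[[1]][!mis], res$completed[[2]][!mis])
  # reproducible under the same seed
  res2 <- impute_mi_pcr_all(inc, npc = 8, m = 3, seed = 8)
  expect_identical(res$completed, res2$completed)
  # complete data: component extraction runs, imputation is vacuous
  resc <- impute_mi_pcr_all(sim$X, npc = 5, m = 2, seed = 9)
  expect_identical(resc$completed[[1]], resc$completed[[2]])
})

test_that("vbv with all components reparameterizes raw-predictor imputation", {
  # with npc = p - 1 the score block spans the same column space as the raw
  # predictors, so pooled estimates agree up to Monte Carlo noise
  est_vbv <- est_raw <- numeric(6)
  for (s in 1:6) {
    x <- toy_incomplete(n = 200, p = 8, prop = 0.3, seed = 20 + s)
    rv <- impute_mi_pcr_vbv(x, npc = 7, m = 5, maxit = 8, seed = 30 + s)
    specs <- list(mi_model_spec("x1", predictors = paste0("x", 2:8)))
    rr <- run_mice(x, specs, m = 5, maxit = 8, seed = 30 + s)
    pv <- pool_moments(rv, c("x1", "x2"))
    pr <- pool_moments(rr, c("x1", "x2"))
    est_vbv[s] <- pv$estimate[pv$estimand == "cor(x1,x2)"]
    est_raw[s] <- pr$estimate[pr$estimand == "cor(x1,x2)"]
  }
  expect_lt(abs(mean(est_vbv) - mean(est_raw)), 0.05)
})

test_that("vbv runs end to end and leaves complete data unchanged", {
  sim <- generate_data(build_design(0), n = 200, n_cat = Inf, seed = 40)
  inc <- impose_mar(sim, 0.3)
  res <- impute_mi_pcr_vbv(inc, npc = 8, m = 2, maxit = 2, seed = 41)
  expect_false(anyNA(res$completed[[1]]))
  obs <- !is.na(inc$data)
  expect_identical(res$completed[[2]][obs], inc$data[obs])
  resc <- impute_mi_pcr_vbv(sim$X, npc = 8, m = 2, maxit = 1, seed = 42)
  expect_identical(resc$completed[[1]], sim$X)
})

test_that("component counts are capped by the observed-case budget", {
  set.seed(50)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("x", 1:12)))
  x[1:18, 1] <- NA                      # 12 observed cases -> cap at 10
  expect_warning(res <- impute_mi_pcr_vbv(x, npc = 11, m = 2, maxit = 2,
                                          seed = 51),
                 "capped")
  expect_false(anyNA(res$completed[[1]]))
})

test_that("comparator methods impute through the same engine", {
  sim <- generate_data(build_design(0), n = 300, n_cat = 5, seed = 60)
  inc <- impose_mar(sim, 0.3)
  rq <- impute_mi_qp(inc, threshold = 0.1, m = 2, maxit = 3, seed = 61)
  ro <- impute_mi_or(inc, study1_targets, study1_mar, m = 2, maxit = 3,
                     seed = 62)
  for (r in list(rq, ro)) {
    expect_false(anyNA(r$completed[[1]]))
    obs <- !is.na(inc$data)
    expect_identical(r$completed[[1]][obs], inc$data[obs])
  }
  # pmm variants stay within the observed support of each target
  rp <- impute_mi_or(inc, study1_targets, study1_mar, m = 2, maxit = 3,
                     seed = 63, method = "pmm")
  for (j in 1:4) {
    mis <- is.na(inc$data[, j])
    expect_true(all(rp$completed[[1]][mis, j] %in% inc$data[!mis, j]))
  }
})
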