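#' Single imputation used to enable component extraction
#'
#' Runs one chain of the chained-equations algorithm (m = 1) with
#' correlation-thresholding predictor selection and returns the single
#' completed matrix.  The fill exists only so that a PCA can be computed on
#' complete data; its imputations are never used for inference.  Targets for
#' which no predictor passes the threshold fall back to an intercept-only
#' sampler (with a message).
#'
#' @param data `incomplete_data` or matrix with `NA` cells.
#' @param threshold Correlation threshold for predictor selection
#'   (default 0.3).
#' @param maxit Sweeps of the single chain (default 20).
#' @param method Sampler, `"bayes-norm"` or `"pmm"`.
#' @param seed Optional integer seed.
#' @return A complete numeric matrix; observed cells are untouched.
#' @export
single_impute_pretreat <- function(data, threshold = 0.3, maxit = 20L,
                                   method = c("bayes-norm", "pmm"),
                                   seed = NULL) {
  method <- match.arg(method)
  data <- as_incomplete(data)
  if (!anyNA(data$data)) return(data$data)
  incomplete <- colnames(data$data)[colSums(data$response) > 0]
  specs <- lapply(incomplete, function(tg) {
    ps <- quickpred_select(data, tg, threshold)
    if (length(ps$predictors) == 0) {
      message("pretreat: no predictor passed threshold for ", tg,
              "; using intercept-only model")
    }
    mi_model_spec(tg, method = method, predictors = ps$predictors)
  })
  run_mice(data, specs, m = 1L, maxit = maxit, seed = seed)$completed[[1]]
}

## resolve an npc request ("max" or integer) against an upper bound
resolve_npc <- function(npc, max_npc, what) {
  if (identical(npc, "max")) return(as.integer(max_npc))
  npc <- as.integer(npc)
  if (npc < 1 || npc > max_npc) {
    stop("`npc` must be between 1 and ", max_npc, " for ", what,
         call. = FALSE)
  }
  npc
}

## cap npc so each univariate normal model keeps positive residual df
cap_npc <- function(npc, n_obs_min, n_raw) {
  cap <- n_obs_min - n_raw - 2L
  if (npc > cap) {
    warning("`npc` capped at ", cap, " (only ", n_obs_min,
            " observed cases for some target)", call. = FALSE)
    npc <- cap
  }
  max(npc, 1L)
}

#' Multiple imputation with components of the auxiliary variables
#'
#' The analysis-model columns are imputed by chained equations using, as
#' predictors, the raw remaining analysis columns plus the leading `npc`
#' principal-component scores of the auxiliary columns (every column not in
#' `analysis_cols`).  The auxiliary block is single-imputed first if it has
#' missing cells, one PCA is fitted on it, and the resulting scores stay
#' fixed for the whole run.
#'
#' @param data `incomplete_data` or matrix with `NA` cells.
#' @param analysis_cols Names of the analysis-model columns.
#' @param npc Number of auxiliary components, or `"max"` (the number of
#'   auxiliary columns, bounded by `n - 1`).
#' @param m Number of imputations.
#' @param maxit Sweeps per chain.
#' @param seed Optional integer seed.
#' @param method Sampler for the main run.
#' @param pretreat List of options for [single_impute_pretreat()]
#'   (`threshold`, `maxit`, `method`), used only when the auxiliary block is
#'   incomplete.
#' @return An `mi_result`.
#' @export
impute_mi_pcr_aux <- function(data, analysis_cols, npc = "max", m = 5L,
                              maxit = 20L, seed = NULL,
                              method = c("bayes-norm", "pmm"),
                              pretreat = list()) {
  method <- match.arg(method)
  data <- as_incomplete(data)
  cols <- colnames(data$data)
  if (!all(analysis_cols %in% cols)) {
    stop("unknown analysis column(s)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  aux_cols <- setdiff(cols, analysis_cols)
  if (length(aux_cols) == 0) stop("no auxiliary columns", call. = FALSE)
  npc <- resolve_npc(npc, min(length(aux_cols), nrow(data$data) - 1L),
                     "components of the auxiliary set")

  aux <- data$data[, aux_cols, drop = FALSE]
  if (anyNA(aux)) {
    po <- utils::modifyList(list(threshold = 0.3, maxit = 20L,
                                 method = "bayes-norm"), pretreat)
    filled <- single_impute_pretreat(data, threshold = po$threshold,
                                     maxit = po$maxit, method = po$method)
    aux <- filled[, aux_cols, drop = FALSE]
  }

  n_obs_min <- min(nrow(data$data) - colSums(data$response))
  npc <- cap_npc(npc, n_obs_min, length(analysis_cols) - 1L)
  basis <- fit_pca(aux, q = npc)

  incomplete <- cols[colSums(data$response) > 0]
  specs <- lapply(incomplete, function(tg) {
    mi_model_spec(tg, method = method,
                  predictors = setdiff(analysis_cols, tg),
                  pcr = list(scores = basis$scores, npc = npc))
  })
  run_mice(data, specs, m = m, maxit = maxit)
}

#' Multiple imputation with components of all variables
#'
#' A single imputation first completes the whole matrix, one PCA is fitted
#' on all `p` columns, and every incomplete variable is then imputed with
#' the leading `npc` scores as its only predictors.  Because the component
#' scores are complete and fixed, a single sweep suffices; the `m`
#' imputations are `m` independent posterior draws from the same design.
#'
#' @inheritParams impute_mi_pcr_aux
#' @param npc Number of components, or `"max"` (`p`, bounded by `n - 1`).
#' @return An `mi_result`.
#' @export
impute_mi_pcr_all <- function(data, npc = "max", m = 5L, seed = NULL,
                              method = c("bayes-norm", "pmm"),
                              pretreat = list()) {
  method <- match.arg(method)
  data <- as_incomplete(data)
  if (!is.null(seed)) set.seed(seed)
  npc <- resolve_npc(npc, min(ncol(data$data), nrow(data$data) - 1L),
                     "components of all variables")

  po <- utils::modifyList(list(threshold = 0.3, maxit = 20L,
                               method = "bayes-norm"), pretreat)
  filled <- single_impute_pretreat(data, threshold = po$threshold,
                                   maxit = po$maxit, method = po$method)
  n_obs_min <- min(nrow(data$data) - colSums(data$response))
  npc <- cap_npc(npc, n_obs_min, 0L)
  basis <- fit_pca(filled, q = npc)

  cols <- colnames(data$data)
  incomplete <- cols[colSums(data$response) > 0]
  specs <- lapply(incomplete, function(tg) {
    mi_model_spec(tg, method = method,
                  pcr = list(scores = basis$scores, npc = npc))
  })
  run_mice(data, specs, m = m, maxit = 1L)
}

#' Multiple imputation with variable-by-variable components
#'
#' The full chained-equations loop in which, at every visit of every
#' variable in every iteration, a PCA is re-fitted on all other columns of
#' the current completed matrix and the leading `npc` scores act as the sole
#' predictors of the Bayesian normal sampler.  No pre-processing single
#' imputation is needed.
#'
#' @inheritParams impute_mi_pcr_aux
#' @param npc Number of components, or `"max"` (`p - 1`, bounded by
#'   `n - 1`).
#' @return An `mi_result`.
#' @export
impute_mi_pcr_vbv <- function(data, npc = "max", m = 5L, maxit = 20L,
                              seed = NULL,
                              method = c("bayes-norm", "pmm")) {
  method <- match.arg(method)
  data <- as_incomplete(data)
  if (!is.null(seed)) set.seed(seed)
  npc <- resolve_npc(npc, min(ncol(data$data) - 1L, nrow(data$data) - 1L),
                     "variable-by-variable components")
  n_obs_min <- min(nrow(data$data) - colSums(data$response))
  npc <- cap_npc(npc, n_obs_min, 0L)

  cols <- colnames(data$data)
  incomplete <- cols[colSums(data$response) > 0]
  specs <- lapply(incomplete, function(tg) {
    mi_model_spec(tg, method = method, pcr = list(vbv = TRUE, npc = npc))
  })
  run_mice(data, specs, m = m, maxit = maxit)
}

#' Multiple imputation with correlation-thresholding predictor selection
#'
#' The pragmatic comparator: each incomplete variable is imputed from the
#' raw columns selected by [quickpred_select()] at the given threshold.
#'
#' @inheritParams impute_mi_pcr_aux
#' @param threshold Correlation threshold (default 0.1).
#' @return An `mi_result`.
#' @export
impute_mi_qp <- function(data, threshold = 0.1, m = 5L, maxit = 20L,
                         seed = NULL, method = c("bayes-norm", "pmm")) {
  method <- match.arg(method)
  data <- as_incomplete(data)
  if (!is.null(seed)) set.seed(seed)
  cols <- colnames(data$data)
  incomplete <- cols[colSums(data$response) > 0]
  specs <- lapply(incomplete, function(tg) {
    ps <- quickpred_select(data, tg, threshold)
    mi_model_spec(tg, method = method, predictors = ps$predictors)
  })
  run_mice(data, specs, m = m, maxit = maxit)
}

#' Multiple imputation with oracle predictor selection
#'
#' The idealized comparator: each incomplete variable is imputed from the
#' remaining analysis columns plus the known missingness predictors.
#'
#' @inheritParams impute_mi_pcr_aux
#' @param mar_predictor_cols Columns that drive the missingness mechanism.
#' @return An `mi_result`.
#' @export
impute_mi_or <- function(data, analysis_cols, mar_predictor_cols, m = 5L,
                         maxit = 20L, seed = NULL,
                         method = c("bayes-norm", "pmm")) {
  method <- match.arg(method)
  data <- as_incomplete(data)
  if (!is.null(seed)) set.seed(seed)
  cols <- colnames(data$data)
  incomplete <- cols[colSums(data$response) > 0]
  specs <- lapply(incomplete, function(tg) {
    ps <- oracle_select(tg, analysis_cols, mar_predictor_cols)
    mi_model_spec(tg, method = method, predictors = ps$predictors)
  })
  run_mice(data, specs, m = m, maxit = maxit)
}
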