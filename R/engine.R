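#' Specify a univariate imputation model
#'
#' One chained-equations sweep imputes each incomplete variable from its own
#' univariate model.  A spec names the target column, the sampler, the raw
#' predictor columns, and (optionally) a principal-component predictor block:
#' either a fixed score matrix computed before the run, or the
#' variable-by-variable strategy that re-fits a PCA on all other columns of
#' the current completed matrix at every visit.
#'
#' @param target Target column name.
#' @param method Sampler: `"bayes-norm"` (Bayesian normal linear) or
#'   `"pmm"` (predictive mean matching).
#' @param predictors Character vector of raw predictor columns (may be
#'   empty; must not contain `target`).
#' @param pcr `NULL` for no component block; `list(scores = <n x q matrix>,
#'   npc = <count>)` for a fixed block; or `list(vbv = TRUE, npc = <count>)`
#'   to re-estimate components from all other columns at every visit.
#' @param ridge Ridge stabilization constant for the sampler.
#' @param donors Donor-pool size for `"pmm"`.
#' @return An object of class `mi_model_spec`.
#' @export
mi_model_spec <- function(target, method = c("bayes-norm", "pmm"),
                          predictors = character(), pcr = NULL,
                          ridge = 1e-5, donors = 5L) {
  method <- match.arg(method)
  if (target %in% predictors) {
    stop("`target` must not appear among `predictors`", call. = FALSE)
  }
  if (!is.null(pcr)) {
    if (is.null(pcr$npc) || pcr$npc < 1) {
      stop("`pcr$npc` must be at least 1", call. = FALSE)
    }
    if (is.null(pcr$vbv) && is.null(pcr$scores)) {
      stop("`pcr` needs either fixed `scores` or `vbv = TRUE`", call. = FALSE)
    }
  }
  structure(list(target = target, method = method,
                 predictors = predictors, pcr = pcr,
                 ridge = ridge, donors = as.integer(donors)),
            class = "mi_model_spec")
}

#' Fill missing cells by random draws from the observed values
#'
#' Starting imputations for the chained-equations algorithm: every `NA` cell
#' is replaced by a value sampled uniformly, with replacement, from the
#' observed values of its own column.
#'
#' @param data An `incomplete_data` object or a matrix with `NA` cells.
#' @param seed Optional integer seed.
#' @return List with `filled` (complete matrix) and `response` (0/1 matrix,
#'   1 = originally missing).
#' @export
initial_fill <- function(data, seed = NULL) {
  data <- as_incomplete(data)
  if (!is.null(seed)) set.seed(seed)
  x <- data$data
  for (j in seq_len(ncol(x))) {
    mis <- is.na(x[, j])
    if (!any(mis)) next
    obs <- x[!mis, j]
    if (length(obs) == 0) {
      stop("column ", colnames(x)[j], " has no observed values",
           call. = FALSE)
    }
    x[mis, j] <- sample(obs, sum(mis), replace = TRUE)
  }
  list(filled = x, response = data$response)
}

#' Run the chained-equations imputation algorithm
#'
#' Runs `m` independent chains.  Each chain starts from [initial_fill()] and
#' performs `maxit` sweeps; a sweep visits the incomplete variables in fixed
#' column order, rebuilds the design matrix per the variable's
#' [mi_model_spec()] (raw predictors, fixed component scores, or
#' variable-by-variable PCA on the current completed matrix), and replaces
#' the missing cells with a fresh draw from the spec's sampler.  Observed
#' cells are never modified.  The per-iteration mean and standard deviation
#' of each variable's imputed values are recorded as convergence traces.
#'
#' @param data An `incomplete_data` object or matrix with `NA` cells.
#' @param specs List of [mi_model_spec()], at least one per incomplete
#'   column.
#' @param m Number of imputations (chains).
#' @param maxit Number of sweeps per chain.
#' @param seed Optional integer seed; given the seed the result is exactly
#'   reproducible.
#' @return An object of class `mi_result`: list with `completed` (list of
#'   `m` complete matrices), `traces` (data frame with columns `chain`,
#'   `variable`, `iteration`, `mean`, `sd`), `m`, `maxit`.
#' @export
run_mice <- function(data, specs, m = 5L, maxit = 20L, seed = NULL) {
  data <- as_incomplete(data)
  if (m < 1 || maxit < 1) stop("`m` and `maxit` must be >= 1", call. = FALSE)
  if (inherits(specs, "mi_model_spec")) specs <- list(specs)
  x0 <- data$data
  cols <- colnames(x0)
  for (s in specs) {
    if (!s$target %in% cols) {
      stop("spec target ", s$target, " is not a column of the data",
           call. = FALSE)
    }
    if (!all(s$predictors %in% cols)) {
      stop("spec for ", s$target, " references unknown predictor(s)",
           call. = FALSE)
    }
  }
  incomplete <- cols[colSums(data$response) > 0]
  covered <- vapply(specs, function(s) s$target, character(1))
  if (!all(incomplete %in% covered)) {
    stop("no spec for incomplete column(s): ",
         paste(setdiff(incomplete, covered), collapse = ", "), call. = FALSE)
  }
  ## keep specs for incomplete targets only, in column order
  specs <- specs[match(intersect(cols, incomplete), covered)]

  if (!is.null(seed)) set.seed(seed)
  completed <- vector("list", m)
  tr <- list()
  for (chain in seq_len(m)) {
    st <- initial_fill(data)
    filled <- st$filled
    for (k in seq_len(maxit)) {
      for (s in specs) {
        j <- match(s$target, cols)
        mis <- data$response[, j] == 1L
        des <- build_sweep_design(s, filled, j)
        y_obs <- x0[!mis, j]
        imp <- switch(s$method,
          "bayes-norm" = draw_bayes_norm(y_obs, des[!mis, , drop = FALSE],
                                         des[mis, , drop = FALSE],
                                         ridge = s$ridge),
          "pmm" = draw_pmm(y_obs, des[!mis, , drop = FALSE],
                           des[mis, , drop = FALSE],
                           ridge = s$ridge, donors = s$donors))
        filled[mis, j] <- imp
        tr[[length(tr) + 1L]] <- data.frame(
          chain = chain, variable = s$target, iteration = k,
          mean = mean(imp), sd = stats::sd(imp))
      }
    }
    completed[[chain]] <- filled
  }

  traces <- if (length(tr)) do.call(rbind, tr) else
    data.frame(chain = integer(), variable = character(),
               iteration = integer(), mean = numeric(), sd = numeric())
  structure(list(completed = completed, traces = traces,
                 m = as.integer(m), maxit = as.integer(maxit)),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("Multiple imputation result: m = ", x$m, ", maxit = ", x$maxit,
      ", ", nrow(x$completed[[1]]), " x ", ncol(x$completed[[1]]),
      "\n", sep = "")
  invisible(x)
}

## assemble the design matrix (with intercept) for one univariate model
build_sweep_design <- function(spec, filled, j) {
  n <- nrow(filled)
  raw <- filled[, spec$predictors, drop = FALSE]
  z <- NULL
  if (!is.null(spec$pcr)) {
    npc <- spec$pcr$npc
    if (isTRUE(spec$pcr$vbv)) {
      basis <- fit_pca(filled[, -j, drop = FALSE], q = npc)
      z <- basis$scores
    } else {
      if (npc > ncol(spec$pcr$scores)) {
        stop("`npc` exceeds the number of available component scores",
             call. = FALSE)
      }
      z <- spec$pcr$scores[, seq_len(npc), drop = FALSE]
    }
    colnames(z) <- paste0("PC", seq_len(ncol(z)))
  }
  cbind(`(Intercept)` = rep(1, n), raw, z)
}
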