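#' Configure a Monte Carlo simulation study
#'
#' Collects the factorial design and method grid for [run_study()].  The
#' factorial crosses auxiliary coarseness (`n_cat` in `Inf, 7, 5, 3, 2`)
#' with the proportion of noise variables (`pn` in `0, 0.33, 0.67, 1`);
#' any subset of cells may be requested.
#'
#' @param study Study layout, 1 (56 columns) or 2 (242 columns).
#' @param S Replications per cell.
#' @param n Rows per generated data set.
#' @param n_cat Coarseness levels to run.
#' @param pn Noise-proportion levels to run.
#' @param methods List of method requests; each element is a list with
#'   `method` in `"vbv"`, `"all"`, `"aux"`, `"qp"`, `"or"` and, for the
#'   component methods, `npc` (integer or `"max"`).
#' @param m Imputations per data set.
#' @param maxit Sweeps per chain.
#' @param target_prop Missingness proportion per target column.
#' @param base_seed Base seed; every (replication, cell) derives its own
#'   seed from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(study = 1, S = 100L, n = 500L, n_cat = Inf,
                         pn = 0, methods = list(list(method = "vbv",
                                                     npc = 8L)),
                         m = 5L, maxit = 20L, target_prop = 0.3,
                         base_seed = 1L) {
  stopifnot(S >= 1, all(n_cat %in% c(Inf, 7, 5, 3, 2)),
            all(pn %in% c(0, 0.33, 0.67, 1)))
  for (mt in methods) {
    if (!mt$method %in% c("vbv", "all", "aux", "qp", "or")) {
      stop("unknown method: ", mt$method, call. = FALSE)
    }
  }
  structure(list(study = study, S = as.integer(S), n = as.integer(n),
                 n_cat = n_cat, pn = pn, methods = methods,
                 m = as.integer(m), maxit = as.integer(maxit),
                 target_prop = target_prop,
                 base_seed = as.integer(base_seed)),
            class = "study_config")
}

method_label <- function(mt) {
  if (is.null(mt$npc)) mt$method else paste0(mt$method, "-", mt$npc)
}

rep_seed <- function(base_seed, rep, offset = 0L) {
  as.integer((as.numeric(base_seed) * 100003 + rep * 131 + offset) %%
               2147483647)
}

## dispatch one configured method on one incomplete data set
run_method <- function(mt, inc, analysis_cols, mar_cols, m, maxit, seed) {
  switch(mt$method,
    vbv = impute_mi_pcr_vbv(inc, npc = mt$npc, m = m, maxit = maxit,
                            seed = seed),
    all = impute_mi_pcr_all(inc, npc = mt$npc, m = m, seed = seed),
    aux = impute_mi_pcr_aux(inc, analysis_cols = analysis_cols,
                            npc = mt$npc, m = m, maxit = maxit,
                            seed = seed),
    qp = impute_mi_qp(inc, threshold = if (is.null(mt$threshold)) 0.1
                      else mt$threshold, m = m, maxit = maxit, seed = seed),
    or = impute_mi_or(inc, analysis_cols = analysis_cols,
                      mar_predictor_cols = mar_cols, m = m, maxit = maxit,
                      seed = seed))
}

#' Run a Monte Carlo simulation study
#'
#' For every replication and design cell: generate fully observed data,
#' impose right-tail MAR missingness on the four target items, impute with
#' every configured method, estimate and pool the target moments, and score
#' the pooled estimates against the full-data truth.  A failure in a single
#' (replication, cell, method) is recorded and does not abort the study.
#'
#' @param config A [study_config()].
#' @param verbose Print per-cell progress.
#' @return A list of class `study_result` with `metrics` (one row per cell
#'   x method x estimand), `pooled` (per-replication pooled estimates, long
#'   format), `full` (per-replication full-data estimates), `errors`
#'   (character log), and `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cells <- expand.grid(n_cat = config$n_cat, pn = config$pn,
                       KEEP.OUT.ATTRS = FALSE)
  targets <- paste0("x", 1:4)
  mar_cols <- paste0("x", 5:8)
  labels <- vapply(config$methods, method_label, character(1))

  metrics <- list(); pooled_rows <- list(); full_rows <- list()
  errors <- character()

  for (ci in seq_len(nrow(cells))) {
    n_cat <- cells$n_cat[ci]; pn <- cells$pn[ci]
    design <- build_design(pn = pn, study = config$study)
    cell_id <- paste0("nCat=", n_cat, ",pn=", pn)
    pooled_cell <- lapply(labels, function(l) vector("list", config$S))
    names(pooled_cell) <- labels
    full_cell <- vector("list", config$S)

    for (rep in seq_len(config$S)) {
      seed <- rep_seed(config$base_seed, rep)
      sim <- generate_data(design, n = config$n, n_cat = n_cat, seed = seed)
      inc <- impose_mar(sim, target_prop = config$target_prop)
      full_cell[[rep]] <- estimate_moments(sim$X, targets)

      for (mi in seq_along(config$methods)) {
        mt <- config$methods[[mi]]
        res <- tryCatch(
          run_method(mt, inc, targets, mar_cols, config$m, config$maxit,
                     seed = rep_seed(config$base_seed, rep, offset = mi)),
          error = function(e) e)
        if (inherits(res, "error")) {
          errors <- c(errors, paste0(cell_id, " rep ", rep, " ",
                                     labels[mi], ": ",
                                     conditionMessage(res)))
          next
        }
        pooled_cell[[labels[mi]]][[rep]] <- pool_moments(res, targets)
      }
      if (verbose && rep %% 20 == 0) {
        message(cell_id, ": replication ", rep, "/", config$S)
      }
    }

    for (l in labels) {
      ok <- !vapply(pooled_cell[[l]], is.null, logical(1))
      if (!any(ok)) next
      met <- evaluate_metrics(pooled_cell[[l]][ok], full_cell[ok])
      met$cell <- cell_id; met$n_cat <- n_cat; met$pn <- pn
      met$method <- l
      metrics[[length(metrics) + 1L]] <- met
      for (rep in which(ok)) {
        tab <- pooled_cell[[l]][[rep]]
        tab$cell <- cell_id; tab$method <- l; tab$rep <- rep
        pooled_rows[[length(pooled_rows) + 1L]] <- tab
      }
    }
    for (rep in seq_len(config$S)) {
      tab <- full_cell[[rep]]
      tab$cell <- cell_id; tab$rep <- rep
      full_rows[[length(full_rows) + 1L]] <- tab
    }
  }

  structure(list(metrics = do.call(rbind, metrics),
                 pooled = do.call(rbind, pooled_rows),
                 full = do.call(rbind, full_rows),
                 errors = errors, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study result: ", length(unique(x$metrics$cell)), " cell(s), ",
      length(unique(x$metrics$method)), " method(s), S = ",
      x$config$S, "\n", sep = "")
  if (length(x$errors)) cat("  ", length(x$errors), " failed cell-reps\n")
  invisible(x)
}

#' Distribution of the component-retention rules over simulated data
#'
#' Applies the four non-graphical retention rules to `S` data sets per
#' design cell, on the fully observed (coarsened) data and/or on the
#' complete cases left after imposing missingness, and summarizes the
#' selected counts by their minimum, median, and maximum.
#'
#' @param study Study layout (1 or 2).
#' @param S Replications per cell.
#' @param n Rows per data set.
#' @param n_cat,pn Design-cell levels to run (crossed).
#' @param rules Subset of `c("oc", "af", "kc", "pa")`.
#' @param sources Subset of `c("fully-observed", "complete-cases")`.
#' @param target_prop Missingness proportion (for the complete-case
#'   source).
#' @param pa_reps Simulated data sets for parallel analysis.
#' @param base_seed Base seed.
#' @return Long-format data frame: one row per (cell, rule, source) with
#'   `min`, `median`, `max` of the selected counts and `S_ok`, the number
#'   of replications in which the source was available.
#' @export
run_npc_table <- function(study = 1, S = 100L, n = 500L, n_cat = Inf,
                          pn = 0, rules = c("oc", "af", "kc", "pa"),
                          sources = c("fully-observed", "complete-cases"),
                          target_prop = 0.3, pa_reps = 100L,
                          base_seed = 1L) {
  rules <- match.arg(rules, several.ok = TRUE)
  sources <- match.arg(sources, several.ok = TRUE)
  cells <- expand.grid(n_cat = n_cat, pn = pn, KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    design <- build_design(pn = cells$pn[ci], study = study)
    counts <- array(NA_integer_,
                    dim = c(S, length(rules), length(sources)),
                    dimnames = list(NULL, rules, sources))
    for (rep in seq_len(S)) {
      seed <- rep_seed(base_seed, rep)
      sim <- generate_data(design, n = n, n_cat = cells$n_cat[ci],
                           seed = seed)
      for (src in sources) {
        prof <- tryCatch({
          if (src == "fully-observed") {
            eigen_profile(sim$X, source = "fully-observed")
          } else {
            inc <- impose_mar(sim, target_prop = target_prop)
            eigen_profile(inc, source = "complete-cases")
          }
        }, error = function(e) NULL)
        if (is.null(prof)) next
        for (r in rules) {
          counts[rep, r, src] <- select_npc(
            prof, rule = r, reps = pa_reps,
            seed = rep_seed(base_seed, rep, offset = 9L))
        }
      }
    }
    for (src in sources) {
      for (r in rules) {
        v <- counts[, r, src]
        out[[length(out) + 1L]] <- data.frame(
          study = study, P = sum(design$items_per_factor),
          n_cat = cells$n_cat[ci], pn = cells$pn[ci], rule = r,
          source = src, min = suppressWarnings(min(v, na.rm = TRUE)),
          median = stats::median(v, na.rm = TRUE),
          max = suppressWarnings(max(v, na.rm = TRUE)),
          S_ok = sum(!is.na(v)), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Impute a CSV data set and report pooled means
#'
#' Generic entry point for user data: reads a CSV with a declared `NA`
#' token, imputes it with the chosen method, optionally writes the `m`
#' completed data sets and the convergence traces, and returns the pooled
#' means of the analysis columns.  With several seeds the whole procedure
#' is repeated per seed so the between-seed spread of the pooled means can
#' be inspected.
#'
#' @param file CSV path (header row required; numeric columns).
#' @param analysis_cols Analysis column names (defaults to the incomplete
#'   columns).
#' @param method `"vbv"`, `"all"`, `"aux"`, `"qp"`, or `"or"`.
#' @param npc Components for the component methods (integer or `"max"`).
#' @param m,maxit Imputations and sweeps.
#' @param seeds One or more integer seeds.
#' @param na_token String coding missing cells in the CSV.
#' @param mar_predictor_cols Required for `method = "or"`.
#' @param out_prefix If non-`NULL`, write `<prefix>_imp<i>.csv` per
#'   imputation, `<prefix>_traces.csv`, and a JSON sidecar
#'   `<prefix>_meta.json` for the first seed.
#' @param sampler Univariate sampler (`"pmm"` is the customary choice for
#'   real survey items; `"bayes-norm"` for continuous data).
#' @return A list with `pooled` (pooled moment table, first seed),
#'   `means_by_seed` (matrix of pooled means, seeds x analysis columns),
#'   and `result` (the `mi_result` of the first seed).
#' @export
run_dataset <- function(file, analysis_cols = NULL, method = "vbv",
                        npc = "max", m = 5L, maxit = 20L, seeds = 1L,
                        na_token = "NA", mar_predictor_cols = NULL,
                        out_prefix = NULL,
                        sampler = c("pmm", "bayes-norm")) {
  sampler <- match.arg(sampler)
  x <- as.matrix(utils::read.csv(file, na.strings = na_token))
  storage.mode(x) <- "double"
  inc <- as_incomplete(x)
  incomplete <- colnames(x)[colSums(inc$response) > 0]
  if (is.null(analysis_cols)) analysis_cols <- incomplete
  if (length(incomplete) == 0) {
    ## nothing to impute: the report is a direct computation
    est <- estimate_moments(x, analysis_cols)
    return(list(pooled = est,
                means_by_seed = matrix(est$estimate[est$type == "mean"],
                                       nrow = 1,
                                       dimnames = list(NULL, analysis_cols)),
                result = NULL))
  }

  mt <- list(method = method, npc = npc)
  first <- NULL; first_pooled <- NULL
  means <- matrix(NA_real_, length(seeds), length(analysis_cols),
                  dimnames = list(NULL, analysis_cols))
  for (si in seq_along(seeds)) {
    res <- run_method(mt, inc, analysis_cols, mar_predictor_cols,
                      m = m, maxit = maxit, seed = seeds[si])
    pooled <- pool_moments(res, analysis_cols)
    means[si, ] <- pooled$estimate[pooled$type == "mean"]
    if (si == 1L) { first <- res; first_pooled <- pooled }
  }

  if (!is.null(out_prefix)) {
    for (i in seq_len(first$m)) {
      utils::write.csv(as.data.frame(first$completed[[i]]),
                       paste0(out_prefix, "_imp", i, ".csv"),
                       row.names = FALSE)
    }
    utils::write.csv(first$traces, paste0(out_prefix, "_traces.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(method = method, npc = npc, m = m, maxit = maxit,
           seeds = seeds, analysis_cols = analysis_cols,
           na_token = na_token, file = file),
      paste0(out_prefix, "_meta.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(pooled = first_pooled, means_by_seed = means, result = first)
}
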