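#' Correlation-thresholding predictor selection
#'
#' Selects, for one imputation target, every column whose absolute Pearson
#' correlation with the target *or* with the target's missingness indicator
#' reaches `threshold`.  Correlations are computed on pairwise-complete
#' cases; constant columns are excluded.  This is the classic
#' quickpred-style strategy used by the correlation-thresholding comparator.
#'
#' @param data An `incomplete_data` object or matrix with `NA` cells.
#' @param target Target column name.
#' @param threshold Correlation threshold in `[0, 1]`.
#' @return An object of class `predictor_set`: list with `target`,
#'   `predictors` (column names in column order), `rule`, `threshold`.
#' @export
quickpred_select <- function(data, target, threshold = 0.1) {
  data <- as_incomplete(data)
  x <- data$data
  if (!target %in% colnames(x)) stop("unknown target", call. = FALSE)
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  j <- match(target, colnames(x))
  y <- x[, j]
  if (all(is.na(y))) stop("target has no observed values", call. = FALSE)
  delta <- as.numeric(is.na(y))
  keep <- logical(ncol(x))
  for (v in seq_len(ncol(x))) {
    if (v == j) next
    xv <- x[, v]
    if (stats::sd(xv, na.rm = TRUE) %in% c(0, NA)) next
    r_y <- suppressWarnings(
      stats::cor(y, xv, use = "pairwise.complete.obs"))
    r_d <- if (stats::sd(delta) == 0) 0 else suppressWarnings(
      stats::cor(delta, xv, use = "pairwise.complete.obs"))
    r <- max(abs(c(r_y, r_d)), na.rm = TRUE)
    keep[v] <- is.finite(r) && r >= threshold
  }
  structure(list(target = target, predictors = colnames(x)[keep],
                 rule = "quickpred", threshold = threshold),
            class = "predictor_set")
}

#' Oracle predictor selection
#'
#' The idealized comparator: the predictors are the remaining analysis-model
#' variables plus the known predictors of missingness, independent of the
#' data realization.
#'
#' @param target Target column name (must be an analysis column).
#' @param analysis_cols Analysis-model column names.
#' @param mar_predictor_cols Columns that drive the missingness mechanism.
#' @return A `predictor_set`.
#' @export
oracle_select <- function(target, analysis_cols, mar_predictor_cols) {
  if (!target %in% analysis_cols) {
    stop("`target` must be one of `analysis_cols`", call. = FALSE)
  }
  preds <- unique(c(setdiff(analysis_cols, target),
                    setdiff(mar_predictor_cols, target)))
  structure(list(target = target, predictors = preds,
                 rule = "oracle", threshold = NA_real_),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("Predictor set for ", x$target, " (", x$rule, "): ",
      paste(x$predictors, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Eigenvalue profile of a data set
#'
#' Eigendecomposes the Pearson correlation matrix of either the full data
#' (assumed fully observed) or of the complete cases of an incomplete data
#' set, the two inputs the component-retention rules are applied to.
#'
#' @param data Matrix, or `incomplete_data` (required for
#'   `source = "complete-cases"`).
#' @param source `"fully-observed"` or `"complete-cases"`.
#' @return An object of class `eigen_profile`: list with `eigenvalues`
#'   (descending), `n` (rows used), `p`, `source`.
#' @export
eigen_profile <- function(data, source = c("fully-observed",
                                           "complete-cases")) {
  source <- match.arg(source)
  x <- if (inherits(data, "incomplete_data")) data$data else as.matrix(data)
  if (source == "complete-cases") {
    x <- x[stats::complete.cases(x), , drop = FALSE]
    if (nrow(x) < ncol(x) + 2L) {
      stop("only ", nrow(x), " complete cases for ", ncol(x),
           " variables; need at least p + 2", call. = FALSE)
    }
  } else if (anyNA(x)) {
    stop("fully-observed source requires complete data", call. = FALSE)
  }
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  structure(list(eigenvalues = pmax(ev, 0), n = nrow(x), p = ncol(x),
                 source = source),
            class = "eigen_profile")
}

#' Non-graphical rules for the number of components
#'
#' Implements four scree-based retention rules:
#' \describe{
#'   \item{`kc`}{Kaiser criterion: the number of eigenvalues above 1.}
#'   \item{`pa`}{Parallel analysis: the number of observed eigenvalues
#'     exceeding the mean eigenvalues of `reps` independent standard-normal
#'     data sets of the same `n x p` (counted while consecutive from the
#'     first).}
#'   \item{`oc`}{Optimal coordinates: component `i` is retained while its
#'     eigenvalue exceeds the value predicted at position `i` by the line
#'     through the next eigenvalue and the last one; the count stops at the
#'     first failure.}
#'   \item{`af`}{Acceleration factor: the scree's sharpest bend is located
#'     at the maximum second difference of the eigenvalues, and the
#'     components before the bend are retained.}
#' }
#' All rules return at least 1.
#'
#' @param profile An [eigen_profile()], or a complete data matrix (a profile
#'   is computed from it; a matrix is required for `rule = "pa"` unless `n`
#'   is given in the profile).
#' @param rule One of `"oc"`, `"af"`, `"kc"`, `"pa"`.
#' @param reps Simulated data sets for parallel analysis.
#' @param quantile Summary of the reference eigenvalues for parallel
#'   analysis: `NULL` uses the mean; a probability (e.g. 0.95) uses that
#'   quantile.
#' @param seed Optional seed for the parallel-analysis simulation.
#' @return Integer count of components to retain.
#' @export
select_npc <- function(profile, rule = c("kc", "pa", "oc", "af"),
                       reps = 100L, quantile = NULL, seed = NULL) {
  rule <- match.arg(rule)
  if (!inherits(profile, "eigen_profile")) {
    profile <- eigen_profile(profile, source = "fully-observed")
  }
  ev <- profile$eigenvalues
  p <- length(ev)
  out <- switch(rule,
    kc = sum(ev > 1),
    pa = {
      if (is.null(profile$n)) stop("parallel analysis needs `n`",
                                   call. = FALSE)
      if (!is.null(seed)) set.seed(seed)
      ref <- matrix(0, reps, p)
      for (r in seq_len(reps)) {
        ref[r, ] <- eigen(stats::cor(matrix(stats::rnorm(profile$n * p),
                                            profile$n, p)),
                          symmetric = TRUE, only.values = TRUE)$values
      }
      thr <- if (is.null(quantile)) colMeans(ref) else
        apply(ref, 2L, stats::quantile, probs = quantile, names = FALSE)
      exceed <- ev > thr
      if (!exceed[1]) 1L else which.min(c(exceed, FALSE)) - 1L
    },
    oc = {
      ## predicted eigenvalue at i from the line through (i+1, ev[i+1]) and
      ## (p, ev[p]); retain while observed > predicted, stop at first failure
      noc <- 1L
      for (i in seq_len(p - 2L)) {
        slope <- (ev[p] - ev[i + 1L]) / (p - (i + 1L))
        pred <- ev[i + 1L] + slope * (i - (i + 1L))
        if (ev[i] <= pred) { noc <- i - 1L; break }
        noc <- i
      }
      max(noc, 1L)
    },
    af = {
      ## second differences ev[i-1] - 2 ev[i] + ev[i+1], i = 2..p-1; the
      ## elbow is at the maximizing i, and i - 1 components precede it
      if (p < 3L) 1L else {
        d2 <- ev[1:(p - 2L)] - 2 * ev[2:(p - 1L)] + ev[3:p]
        max(which.max(d2), 1L)
      }
    })
  max(as.integer(out), 1L)
}
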