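#' Build the latent design of a simulation study
#'
#' Constructs the confirmatory-factor-model generating design used by the
#' Monte Carlo studies: seven latent factors measured through a simple
#' structure (every item loads on exactly one factor with loading
#' \eqn{\lambda = 0.85}), unit latent variances, and a latent correlation
#' matrix whose off-diagonal entries are either 0.7 ("signal" factors) or
#' 0.1 ("noise" factors).  The first factor carries the analysis items (four
#' imputation targets plus four predictors of missingness); the remaining six
#' factors carry the pool of potential auxiliary items.
#'
#' @param pn Proportion of noise variables among the auxiliary items; one of
#'   0, 0.33, 0.67, 1.  `round(pn * 6)` of the six auxiliary factors are set
#'   to correlate 0.1 with every other factor; all remaining pairs correlate
#'   0.7.
#' @param study Study layout: `1` gives 8 items per factor (56 columns),
#'   `2` keeps 8 items on the first factor and uses 39 items on each
#'   auxiliary factor (242 columns).
#'
#' @return An object of class `latent_design`: a list with elements
#'   `n_factors`, `items_per_factor`, `loading`, `psi`, `error_var`,
#'   `target_mean`, `target_var`, `pn`, `study`, and the derived column role
#'   vector `roles` (`"T"`, `"M"`, `"A"`).
#'
#' @examples
#' d <- build_design(pn = 0.33, study = 1)
#' sum(d$items_per_factor)           # 56 columns
#' table(d$psi[lower.tri(d$psi)])    # mix of 0.1 and 0.7
#' @export
build_design <- function(pn = 0, study = 1) {
  if (length(pn) != 1 || !pn %in% c(0, 0.33, 0.67, 1)) {
    stop("`pn` must be one of 0, 0.33, 0.67, 1", call. = FALSE)
  }
  if (length(study) != 1 || !study %in% c(1, 2)) {
    stop("`study` must be 1 or 2", call. = FALSE)
  }
  n_factors <- 7L
  items_aux <- if (study == 1) 8L else 39L
  items_per_factor <- c(8L, rep(items_aux, 6L))

  loading <- 0.85
  n_noise <- as.integer(round(pn * 6))
  ## factors 2..7 are auxiliary; the last `n_noise` of them are flagged as
  ## noise: every correlation involving a noise factor is 0.1, pairs of
  ## signal factors stay at 0.7
  noise <- rep(FALSE, n_factors)
  if (n_noise > 0) noise[(n_factors - n_noise + 1L):n_factors] <- TRUE
  psi <- matrix(0.7, n_factors, n_factors)
  for (j in seq_len(n_factors)) {
    if (noise[j]) {
      psi[j, ] <- 0.1
      psi[, j] <- 0.1
    }
  }
  diag(psi) <- 1

  ## positive definiteness guard (holds for all four pn levels)
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent correlation matrix is not positive definite",
                         call. = FALSE)

  p <- sum(items_per_factor)
  roles <- c(rep("T", 4L), rep("M", 4L), rep("A", p - 8L))

  structure(
    list(
      n_factors = n_factors,
      items_per_factor = items_per_factor,
      loading = loading,
      psi = psi,
      error_var = 1 - loading^2,
      target_mean = 5,
      target_var = 6.5,
      pn = pn,
      study = as.integer(study),
      noise_factors = which(noise),
      roles = roles
    ),
    class = "latent_design"
  )
}

#' @export
print.latent_design <- function(x, ...) {
  cat("Latent design (study ", x$study, ")\n", sep = "")
  cat("  factors: ", x$n_factors,
      ", items per factor: ", paste(x$items_per_factor, collapse = "/"),
      " (p = ", sum(x$items_per_factor), ")\n", sep = "")
  cat("  loading lambda = ", x$loading,
      ", error variance = ", format(x$error_var), "\n", sep = "")
  cat("  pn = ", x$pn, " (noise factors: ",
      if (length(x$noise_factors)) paste(x$noise_factors, collapse = ", ")
      else "none", ")\n", sep = "")
  invisible(x)
}

#' Population item correlation matrix implied by a latent design
#'
#' Closed form of the model-implied correlation matrix: 1 on the diagonal,
#' \eqn{\lambda^2} for two items of the same factor, and
#' \eqn{\lambda^2 \psi_{jk}} for items of different factors.  Used as the
#' analytic reference for correlation-recovery and eigenvalue checks.
#'
#' @param design A `latent_design`.
#' @return A `p x p` correlation matrix.
#' @export
population_cor <- function(design) {
  stopifnot(inherits(design, "latent_design"))
  lambda <- make_loadings(design)
  r <- lambda %*% design$psi %*% t(lambda)
  diag(r) <- 1
  r
}

## p x 7 loading matrix with simple structure
make_loadings <- function(design) {
  p <- sum(design$items_per_factor)
  lambda <- matrix(0, p, design$n_factors)
  row <- 1L
  for (f in seq_len(design$n_factors)) {
    k <- design$items_per_factor[f]
    lambda[row:(row + k - 1L), f] <- design$loading
    row <- row + k
  }
  lambda
}
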