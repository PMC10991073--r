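---
title: "Chained-equations imputation with principal component regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chained-equations imputation with principal component regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipcr)
```

## The many-variables problem

Multiple imputation by chained equations (MICE, also called fully
conditional specification) imputes an incomplete data set by cycling
through its incomplete variables: for each target $x_j$ a univariate model
$f(x_j \mid X_{-j}, \theta_j)$ is fitted on the currently completed data,
parameters are drawn from their posterior, and the missing cells are
replaced by draws from the posterior predictive distribution.  With
hundreds of candidate predictors — the normal situation in social-science
surveys — putting all of $X_{-j}$ into every univariate model is unstable
or impossible (collinearity, $p > n_{obs}$), and hand-selecting predictors
requires expertise that is not always available.

`mipcr` addresses this by **principal component regression inside the
chained-equations loop**: each univariate model regresses the target on a
small number $q$ of principal-component scores instead of the raw
predictors.  Three placements of the PCA are implemented:

* **Auxiliary components** (`impute_mi_pcr_aux`): one PCA on the
  auxiliary block (everything outside the analysis model), fitted once
  before the run; univariate models use the raw remaining analysis
  variables plus the leading $q$ auxiliary scores.  Requires the analysis
  model to be known, and the auxiliary block to be complete (a
  single-imputation pretreatment fills it if not).
* **All-variable components** (`impute_mi_pcr_all`): a pretreatment single
  imputation completes the whole matrix, one PCA is fitted on all columns,
  and each target is imputed with the leading $q$ scores as its only
  predictors.  Because the predictors are complete and fixed, one sweep
  suffices; the $m$ imputations are independent posterior draws.
* **Variable-by-variable components** (`impute_mi_pcr_vbv`): at every
  visit of every variable in every iteration, a fresh PCA is fitted on all
  other columns of the current completed matrix and the leading $q$ scores
  act as predictors.  No pretreatment and no analysis-model knowledge
  needed, at a higher computational price.

Two comparators close the design space: correlation thresholding
(`impute_mi_qp`, the quickpred-style strategy: keep predictors whose
absolute correlation with the target or its missingness indicator reaches
a threshold, default 0.1) and the oracle (`impute_mi_or`: the remaining
analysis variables plus the true missingness predictors — available only
in simulation).

## Samplers and pooling

The univariate sampler is Bayesian imputation under the normal linear
model: $\sigma^{2*} = \mathrm{SSR}/\chi^2_{\nu}$ with
$\nu = n_{obs} - q$ (floored at 1), $\beta^* \sim N(\hat\beta,
\sigma^{2*}(X'X + \kappa I)^{-1})$, imputations
$X_{mis}\beta^* + N(0, \sigma^{2*})$.  The ridge constant
$\kappa = 10^{-5}$ stabilizes near-collinear designs and is configurable.
Predictive mean matching (`draw_pmm`) reuses the same parameter draw and
returns observed donor values (type-1 matching, donor pool 5, uniform
draw) — the customary choice for real survey items whose distributions
the normal model cannot mimic.

Moment estimates are pooled by Rubin's rules on transformed scales chosen
so that intervals respect the parameter space: means on the identity
scale, variances on the log scale, covariances untransformed, correlations
on the Fisher-z scale with $SE = 1/\sqrt{n-3}$.  Total variance is
$T = \bar U + (1 + 1/m)B$ and degrees of freedom follow Barnard–Rubin with
complete-data df $n - 1$ (at $n = 500$, $m = 5$ the small-sample
adjustment is not negligible for coverage).  Intervals are back-transformed,
so correlation intervals always lie inside $(-1, 1)$.

## The Monte Carlo laboratory

`run_study()` reproduces, at a configurable scale, a factorial evaluation
of these methods on data generated from a seven-factor confirmatory factor
model: $X = F\Lambda' + E$, simple structure, loadings $\lambda = 0.85$,
unit latent variances, error variance $1 - \lambda^2$.  The first factor
carries eight items: four imputation targets ($T$) and four missingness
predictors ($M$); the remaining six factors carry the auxiliary pool
($A$; 8 items each in study 1, $p = 56$, or 39 each in study 2,
$p = 242$).  Columns are rescaled with sample moments to mean 5 /
variance 6.5 (Likert-like 10-point items), so generated columns hit those
moments exactly by construction.

Two design factors are crossed:

* `pn` $\in \{0, 0.33, 0.67, 1\}$ — the proportion of *noise* auxiliary
  factors, implemented through the latent correlations: a noise factor
  correlates 0.1 with every other factor, signal pairs correlate 0.7.
  Only the count of noise factors is identified by the design; this
  package flags the *last* `round(pn * 6)` auxiliary factors, and sets
  every correlation involving a noise factor to 0.1 — the simplest
  positive-definite completion.
* `n_cat` $\in \{\infty, 7, 5, 3, 2\}$ — the auxiliary items (M and A) are
  coarsened to this many categories by equal-probability sample-quantile
  cuts labelled $1..n_{cat}$ (balanced categories, the common recipe for
  simulated Likert items).  Targets stay continuous.  PCA always operates
  on the Pearson correlation matrix of the (possibly coarsened) data,
  treating ordinal levels as numeric.

Missingness is right-tail MAR: for each target column independently,
$\mathrm{logit}\,P(\delta = 1) = \beta_0 + s(M\mathbf{1})$, where
$s(\cdot)$ standardizes the weighted sum score to unit variance and
$\beta_0$ is found by bracketed root finding (bracket $[-20, 20]$,
tolerance $10^{-6}$ on the proportion) so the expected missing fraction is
0.30.  Standardizing the score follows standard amputation methodology:
applied to raw variance-6.5 items the unit slopes would make the score's
standard deviation $\approx 9$ and the mechanism an effectively
deterministic cut at the 70th percentile, which is both unrealistic and
inconsistent with how gently even an oracle imputer degrades under this
design.  Coarsening never weakens the mechanism: the score always uses the
continuous $M$.

What the generator deliberately does *not* emulate: non-normal latent
distributions, cross-loadings and correlated errors, MNAR mechanisms,
clustered observations.  Conclusions from these simulations therefore
speak to well-behaved questionnaire-like data; performance on skewed or
hierarchical data must be assessed separately.

## Choosing the number of components

The headline empirical finding the package reproduces is dichotomous: with
at least as many components as generating factors (here 7), all three
PCR placements give small bias and near-nominal coverage; with fewer,
bias and undercoverage can be severe (the variable-by-variable method
with 5 components in the all-noise condition shows relative bias above
20%).  `select_npc()` implements four non-graphical retention rules —
Kaiser (eigenvalues above 1), parallel analysis (observed eigenvalues
above the mean of simulated independent-normal eigenvalues; 100
replicates by default, a quantile variant is exposed), optimal
coordinates, and acceleration factor — applied to the eigenvalues of the
Pearson correlation matrix of either the fully observed data or the
complete cases (`eigen_profile()`).  In this design the Kaiser and
parallel-analysis rules reliably select at least 7 components; the
acceleration factor underestimates (typically 1).  The optimal-coordinates
stop rule is evaluated against the line through the next and the last
eigenvalue; note that on a degenerate profile with tied eigenvalues (such
as the population correlation matrix itself) it stops immediately —
sampling noise is what gives it its typical median of 7 on generated data.

## Numerical choices and edge cases

* PCA component signs are fixed by making the largest-magnitude weight
  positive, so results do not depend on the eigensolver's sign convention.
  Zero-variance columns are rejected by name.
* `npc = "max"` resolves per method: $p - 4$ auxiliary columns for the
  auxiliary strategy in the 56-column design (52), $p$ for all-variables
  (56), $p - 1$ for variable-by-variable (55), all bounded by $n - 1$.
  When a target has few observed cases, `npc` is capped at
  $n_{obs} - (\text{raw predictors}) - 2$ with a warning, preserving
  positive residual degrees of freedom.
* Visit order is fixed left-to-right column order; the $m$ imputations are
  $m$ independent chains; starting imputations are random draws from the
  observed values of each column.  Identical seeds give bit-identical
  results.  In `run_study`, every (replication, cell) derives its own seed
  from the base seed, so any single cell can be re-run in isolation; a
  failing cell is logged, not fatal.
* The all-variables strategy shares one pretreatment fill across the $m$
  imputations (they differ through the posterior draws); this mirrors the
  fact that the pretreatment is never used for inference.
* The pretreatment single imputation selects predictors by correlation
  thresholding at 0.3; a target with no predictor above the threshold
  falls back to an intercept-only sampler with a message.

## Scale of the shipped replications

The packaged tests and the acceptance script run the simulation at
$S = 100$ replications per cell with $n = 500$, $m = 5$, and 20
iterations — enough for the bias and coverage patterns to be stable (the
Monte Carlo standard error of a relative-bias estimate for the target
correlation is well under one percentage point) while keeping a full run
in the minutes range on one CPU.  Published versions of this design
typically use $S = 500$; `study_config(S = 500)` reproduces that scale
unchanged.

## Known limitations

Only continuous imputation targets are supported (the studies impose
missingness on continuous items); logistic or polytomous samplers,
passive imputation, and automatic convergence stopping are out of scope.
PCA is classical (Pearson correlations); robust or mixed-data variants
(PCAMIX, polychoric PCA) could be substituted in principle but are not
implemented.  The amputation module implements logistic right-tail MAR
only.
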