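# mipcr

Multiple imputation by chained equations (MICE / fully conditional
specification) with **principal component regression** as the univariate
imputation model — plus the Monte Carlo machinery to evaluate it.

## Why

In MICE, every incomplete variable $x_j$ gets a univariate imputation
model $f(x_j \mid X_{-j}, \theta_j)$.  When a data set has hundreds of
candidate predictors, specifying these models is the hard part: putting
everything in is numerically fragile (collinearity, more predictors than
observed cases), and selecting by hand requires expertise.  `mipcr`
replaces the raw predictors with the leading $q$ principal-component
scores, $f(x_j \mid Z, \theta_j)$ with $Z = XW$, in three placements:

| Function | Components of | PCA fitted | Notes |
|---|---|---|---|
| `impute_mi_pcr_aux()` | auxiliary variables only | once, before MICE | raw analysis variables stay in the model |
| `impute_mi_pcr_all()` | all variables | once, after a single-imputation pretreat | one sweep suffices |
| `impute_mi_pcr_vbv()` | all other variables | at every visit of every iteration | no pretreat, no analysis-model knowledge |

Comparators `impute_mi_qp()` (correlation thresholding / quickpred-style)
and `impute_mi_or()` (oracle) complete the toolbox, together with Bayesian
normal and predictive-mean-matching samplers (`draw_bayes_norm()`,
`draw_pmm()`), Rubin's-rules pooling with Barnard–Rubin degrees of freedom
(`pool_rubin()`, `pool_moments()`), retention rules for choosing $q$
(`select_npc()`: Kaiser, parallel analysis, optimal coordinates,
acceleration factor), and a simulation laboratory (`generate_data()`,
`impose_mar()`, `run_study()`) that generates seven-factor
confirmatory-factor-model data and imposes calibrated right-tail MAR
missingness.

## Worked example

Generate questionnaire-like data (56 items measuring 7 correlated latent
factors, auxiliary items coarsened to 5 categories), make 30% of the four
target items missing at random through the upper tail of the predictor
score, impute variable-by-variable with 8 components, and pool:

```r
library(mipcr)

design <- build_design(pn = 0, study = 1)
sim    <- generate_data(design, n = 500, n_cat = 5, seed = 2026)
inc    <- impose_mar(sim, target_prop = 0.3)
inc
#> Incomplete data: 500 x 56
#>   per-target missing fraction: 0.338, 0.280, 0.330, 0.292

res    <- impute_mi_pcr_vbv(inc, npc = 8, m = 5, maxit = 20, seed = 2027)
pooled <- pool_moments(res, paste0("x", 1:4))
pooled[pooled$estimand == "cor(x1,x2)",
       c("estimand", "estimate", "ci_lower", "ci_upper", "df")]
#>    estimand  estimate  ci_lower  ci_upper       df
#>  cor(x1,x2) 0.7270913 0.6701107 0.7755526 32.90518
```

The pooled correlation 0.727 (95% CI 0.670–0.776, pooled on the Fisher-z
scale, Barnard–Rubin df 32.9) recovers the full-data value 0.731 that was
lost to the amputation.  How many components are enough?  Apply a
retention rule to the complete cases:

```r
select_npc(eigen_profile(inc, source = "complete-cases"), "kc")
#> [1] 7
```

— the Kaiser criterion finds the seven latent dimensions; using at least
that many components is what makes the imputation above nearly unbiased,
while e.g. `npc = 5` in the same design inflates bias and collapses
interval coverage (see the vignette and the simulation results below).

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mipcr.R", package = "mipcr"))') \
  simulate --study 1 --n 500 --ncat 5 --pn 0 --seed 1 --out data.csv
```

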