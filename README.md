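# discboost

Component-wise gradient boosting for **discrete failure time models**:
variable selection over time-independent effects, time-varying effects and
hierarchy-constrained two-way interactions, with BIC stopping rules,
penalized Newton re-estimation, and a full simulation/evaluation harness.

## Who this is for

Analysts of large registries (cancer surveillance, administrative cohorts)
where event times are recorded on a coarse grid (e.g. months), ties are
massive, and the questions are: *which* covariates matter, do their effects
*change over follow-up*, and which covariate *pairs* interact — all while
keeping the fitted model interpretable as log odds ratios.

## The model and the algorithm

Events occur at grid times `t_1 < ... < t_S`. The hazard of subject `i` at
`t_s` follows a logistic model

```
lambda(t_s; Z_i) = expit{ gamma_s + sum_j phi_j z_ij
                          + sum_j theta_j' B(t_s) z_ij
                          + sum_{j<j'} alpha_jj' z_ij z_ij' }
```

with a **reduced** cubic B-spline basis `B(t)` (`K = 7` functions, first one
dropped) so that `theta_j = 0` is exactly the time-independent model. The
log-likelihood is the sum of Bernoulli terms over each subject's at-risk
intervals, computed by streaming over an `n x S` array — the data are never
expanded into the `sum(T_i)`-row long format.

Selection is component-wise gradient boosting: each iteration refreshes the
baseline by least squares on the gradient, then advances the single
best-fitting candidate term (time-independent effect, whole spline block, or
eligible interaction pair) by a step `nu = 0.5`. Interaction candidates obey
a **strong** (both parents in), **weak** (one parent in) or **no** hierarchy,
updated dynamically as main effects enter. Stopping is by BIC, either with
degrees of freedom from an approximate hat-matrix recursion (*boosting
BIC*), or by refitting the selected structure with penalized Newton
(P-spline or smoothing-spline penalty, smoothing chosen by TIC) every 5th
iteration and using information-based degrees of freedom (*re-estimation
BIC*). The refit also de-shrinks the coefficient estimates and supplies
delta-method confidence bands for hazard-ratio curves.

## A worked example

```r
library(discboost)

# a synthetic cohort: 15 covariates, 5 of them time-varying, 5 true
# interactions under a strong hierarchy (n = 800 subjects, 20 time points)
sim <- simulate_dsurv(scenario_spec("interaction", n = 800, seed = 42))
fit <- disc_boost(sim$dsurv, m_max = 800, stopping = "reestimation_bic",
                  hierarchy = "strong")
fit
#> <disc_boost> component-wise boosting fit
#>   n = 800  P = 15  S = 20
#>   hierarchy: strong  stopping: reestimation_bic
#>   m_stop = 720 of m_max = 800
#>   selected: 12 covariates (8 time-varying), 7 interactions

selected_sets(fit)$int    # truth: (1,2) (1,3) (1,9) (5,10) (6,7)
#>      j jp
#> [1,] 1  2
#> [2,] 1  3
#> [3,] 1  9
#> [4,] 5  7
#> [5,] 5 10
#> [6,] 6  7
#> [7,] 6 10

glance(fit$reest$fit)[, c("p", "loglik", "df", "bic", "lambda")]
#> # A tibble: 1 × 5
#>       p loglik    df   bic lambda
#>   <int>  <dbl> <dbl> <dbl>  <dbl>
#> 1    84  -768.  48.9 1864.    100

# hazard-ratio curve for z1 = 1 vs 0 (other covariates at 0), 95% band;
# the truth at t = 1 is exp(beta_1(1)) = exp(1 + cos(pi/50)) ~ 7.4
hazard_ratio_curve(fit$reest$fit, z1 = c(1, rep(0, 14)), z0 = rep(0, 15))
#> # A tibble: 20 × 5
#>    time estimate    lo    hi se_log
#>   <dbl>    <dbl> <dbl> <dbl>  <dbl>
#> 1     1     7.31  5.71  9.37  0.126
#> 2     2     7.31  5.71  9.37  0.126
#> # ... 18 more rows
```

The selected pair set above is read against the simulation truth stored in
`sim$truth`; `selection_metrics()` turns fits plus truth into
FP/FN/sensitivity/specificity tables, and `replicate_experiment()` /
`estimation_experiment()` run seeded replicate studies of selection and
estimation accuracy.

Every user-facing function takes a data frame (or the `dsurv` container)
first; fitted objects have `tidy()`, `glance()` and `autoplot()` methods. A
thin command-line wrapper with `simulate`, `boost`, `refit`, `curve` and
`replicate` subcommands is installed at `inst/cli/discboost.R`.

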