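# drate

Double-robust estimation of average treatment effects (risk differences)
for a binary exposure and a binary outcome, with a Monte Carlo harness for
benchmarking estimator performance under near-positivity violations and
model misspecification.

The package is built for the population-based cancer-epidemiology setting:
a 1-year mortality indicator $Y$, an exposure $A$ (e.g. cancer diagnosis
through an emergency presentation), and a structural adjustment set
$W = (W_1, W_2, W_3, W_4)$ of socioeconomic status, age, cancer stage and
comorbidity that ensures conditional exchangeability. The target parameter
is the average treatment effect

$$\psi_0 = E[Y(1)] - E[Y(0)],$$

with nuisance functions $g(W) = P(A = 1 \mid W)$ (propensity score) and
$\bar Q(A, W) = E[Y \mid A, W]$ (outcome regression).

## What is in the package

**Estimators** (tibble in, broom-style `tidy()`/`glance()` out):

| function | estimator | inference |
|---|---|---|
| `ate_naive()` | linear-probability regression adjustment (the "naive" comparator) | HC1 robust SE |
| `ate_iptw_ra()` | inverse-probability-weighted regression adjustment, standardised | stacked estimating-equation sandwich |
| `ate_aiptw()` | augmented IPTW (one-step estimating equation) | SD of the summand / √n |
| `ate_tmle()` | targeted maximum likelihood with a super learner | efficient influence curve |

`ate_tmle()` uses a V-fold cross-validated super learner (stepwise AIC
logistic selection, main-terms GLM, GLM with squares + all pairwise
interactions; convex NNLS weights) and bounds the propensity to
[0.025, 0.975]; AIPTW/IPTW-RA instead refuse propensities within `ps_tol`
(default 1e-5) of the boundary.

**Data-adaptive selection**: `bfit_select()` ranks a nested ladder of
candidate logistic models (up to the fully interacted order-2 polynomial)
by AIC/BIC — the "best fit" strategy used with the weighting estimators.

**Synthetic cohorts**: `dgp_scenario1()` / `dgp_scenario2()` are
calibrated structural data-generating processes with a controllable
near-positivity-violation knob; `generate_lung_cohort()` emulates an
English lung-cancer registry cohort calibrated to published conditional
1-year mortality proportions (synthetic — no registry data ships with the
package). `compute_true_ate()` returns the plug-in truth.

**Monte Carlo harness**: `run_scenario()` / `run_monte_carlo()` replicate
the benchmark design (1,000 replications at n = 1,000 / 10,000, or a
scaled desk profile) and report mean estimate, SD, absolute and relative
bias, RMSE and 95% CI coverage per estimator; `report_table()` formats
the benchmark table, `autoplot()` draws sampling distributions and
propensity-overlap diagnostics.

## A worked example

```r
library(drate)

cohort <- generate_cohort(dgp_scenario1(), n = 2000, seed = 7)
tidy(ate_tmle(cohort, sl_v = 5, seed = 7))
#> # A tibble: 1 × 5
#>   method estimate std.error conf.low conf.high
#>   <chr>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 tmle     -0.180    0.0201   -0.220    -0.141

compute_true_ate(dgp_scenario1(), n_mc = 1e6, seed = 1)
#> [1] -0.181416
```

The TMLE estimate (−0.180, 95% CI −0.220 to −0.141) recovers the true
risk difference of −0.181: exposure raises 1-year mortality by about 18
percentage points in this simulated cohort. A small benchmark:

```r
res <- run_scenario(scenario = 1, n = 500, reps = 20, seed = 42,
                    estimators = c("naive", "aiptw", "tmle"))
report_table(res)
#> # A tibble: 3 × 7
#>   estimator `ATE (SD)`      `Absolute bias` `Relative bias, %` RMSE   `Coverage, %` Failed
#>   <chr>     <chr>           <chr>           <chr>              <chr>  <chr>          <int>
#> 1 naive     -0.2210 (0.060) 0.0396          21.8               0.0706 85.0               0
#> 2 aiptw     -0.1809 (0.052) 0.0005          0.3                0.0509 85.0               0
#> 3 tmle      -0.1803 (0.053) 0.0011          0.6                0.0520 85.0               0
```

The naive comparator overestimates the effect magnitude (relative bias
about a fifth at this tiny scale) while the double-robust estimators
centre on the truth — the qualitative pattern the full benchmark
quantifies at 1,000 replications.

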