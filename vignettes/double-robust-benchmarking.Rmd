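---
title: "Double-robust estimation of mortality risk differences: models, estimators, and the Monte Carlo benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-robust estimation of mortality risk differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drate)
library(dplyr)
```

## The estimation problem

`drate` estimates the average treatment effect (ATE) of a binary exposure
$A$ on a binary outcome $Y$ — here framed as the 1-year cancer-mortality
risk difference

$$\psi_0 = E\big[Y(1)\big] - E\big[Y(0)\big],$$

identified under conditional exchangeability given a covariate set
$W = (W_1, \dots, W_4)$: socioeconomic status, age, cancer stage and
comorbidity. These four covariates form the adjustment set of a structural
causal model for population-based cancer epidemiology in which cancer
stage, socioeconomic status and comorbidity constitute the minimal
backdoor adjustment set, and treatment decisions (e.g. whether a cancer is
diagnosed through an emergency presentation) depend on all of them.

Two nuisance functions appear in every estimator:

* the propensity score $g(W) = P(A = 1 \mid W)$, and
* the outcome regression $\bar Q(A, W) = E[Y \mid A, W]$.

The package implements four estimators of $\psi_0$:

1. **Naive regression adjustment** (`ate_naive()`): the coefficient on
   $A$ in a linear-probability OLS regression of $Y$ on $A$ and main-terms
   $W$, with HC1 heteroskedasticity-robust standard errors. This
   coefficient is a conditional-variance-weighted average of conditional
   risk differences, not the ATE: under effect heterogeneity and poor
   overlap it is biased, which is precisely what the benchmark measures.
2. **IPTW-RA** (`ate_iptw_ra()`): arm-specific outcome regressions
   weighted by the unnormalised inverse probability of the observed
   treatment, standardised over the whole sample,
   $\hat\psi = n^{-1}\sum_i [\hat m_1(W_i) - \hat m_0(W_i)]$. Standard
   errors come from the sandwich variance of the stacked estimating
   equations (propensity score, two weighted outcome scores, two means),
   so nuisance estimation is accounted for.
3. **AIPTW** (`ate_aiptw()`): the one-step augmented estimator
   $$\hat\psi = \frac{1}{n}\sum_i \left[ \hat Q(1, W_i) - \hat Q(0, W_i)
     + \frac{A_i (Y_i - \hat Q(1, W_i))}{\hat g(W_i)}
     - \frac{(1 - A_i)(Y_i - \hat Q(0, W_i))}{1 - \hat g(W_i)} \right],$$
   with the standard error equal to the sample standard deviation of the
   summand over $\sqrt n$. It is *not* a substitution estimator: under
   near-positivity violations single summands of size $1/\hat g$ can push
   the estimate outside $[-1, 1]$, and the package deliberately does not
   prevent this (the diagnostics record it).
4. **TMLE** (`ate_tmle()`): the targeted substitution estimator. Initial
   $\bar Q$ and $g$ come from a cross-validated super learner (or
   parametric specs); $g$ is bounded to $[0.025, 0.975]$; the clever
   covariates $H_1 = A/g$, $H_0 = -(1-A)/(1-g)$ enter an intercept-free
   logistic fluctuation with offset $\text{logit}\,\bar Q(A, W)$; the
   updated predictions are plugged in. Standard errors use the efficient
   influence curve. As a substitution estimator the estimate always lies
   in $[-1, 1]$, and after convergence the empirical mean of the
   influence curve is zero by the fluctuation score equations.

Both AIPTW and TMLE are double robust: consistent if either nuisance
model is correctly specified.

## The super learner

TMLE's default nuisance estimator is a V-fold (10-fold by default)
cross-validated convex ensemble over three learners: bidirectional
stepwise logistic selection by AIC (`sl_step`), a main-terms logistic GLM
(`sl_glm`), and a logistic GLM with squares of the continuous predictors
and all pairwise interactions (`sl_glm_interaction`). Ensemble weights
minimise the squared-error risk of the convex combination of held-out
predictions (non-negative least squares, normalised) — the standard
NNLS metalearner; a log-loss metalearner was considered and not
implemented because the squared-error form is both the default of the
ensemble-learning software this mirrors and exactly testable against a
simplex grid search.

Two design choices deserve comment:

* **Stepwise scope.** `sl_step` searches the main-terms scope, matching
  the basic stepwise learner of the ensemble it emulates; a variant over
  mains + all pairwise interactions (`sl_step_interaction`) is available
  but not in the default library. The interaction surface is already
  covered by `sl_glm_interaction`, and the mains-scope search is an order
  of magnitude cheaper inside the Monte Carlo loop.
* **Stratified folds.** Fold assignment balances the binary response
  across folds (cycling fold labels over a shuffle grouped by response).
  At $n = 1{,}000$ with uncommon outcomes, plain random folds
  occasionally produce a fold with no events, which makes learner fits
  degenerate; stratification removes this failure mode and is switchable
  (`stratify = FALSE`).

## Best-fit (AIC/BIC) model selection

`bfit_select()` implements the data-adaptive strategy used with the
weighting estimators: a nested ladder of candidate logistic models —
one main effect, each further main effect, then squares, then pairwise
products, ending at the fully interacted order-2 polynomial (14
non-intercept terms for four covariates) — each fitted by maximum
likelihood and ranked by AIC or BIC. The selection rule is: minimise the
criterion, break ties towards fewer parameters, then towards earlier
enumeration. AIC is the default criterion (the ranking table reports
both, so AIC/BIC disagreement is visible); the enumeration order is fixed
and documented because the exact ladder of the original best-fit tool is
not published.

## The synthetic cohorts

`dgp_scenario1()` and `dgp_scenario2()` are calibrated structural DGPs
over four covariates: `w1` SES quintile (discrete uniform 1–5), `w2` a
continuous age score, `w3` stage I–IV (discrete uniform), `w4` a
comorbidity indicator (Bernoulli, prevalence 0.4). The exposure follows a
logistic propensity model and the outcome a logistic model that always
includes the age-by-comorbidity product `w2:w4`. Near-positivity
violations are produced by the `positivity_severity` knob, which scales
the covariate coefficients of the propensity model
($\eta = \alpha_0 + (1 + s)\sum_j \alpha_j x_j$): severity 0 keeps the
harmless base coefficients, and increasing $s$ pushes the left tail of
the propensity distribution towards zero *without truncating or removing
anyone* — violations are diagnosed (`overlap_summary()`), never silently
repaired.

The exact coefficients were calibrated once, by the documented procedure
in `tools/calibrate_dgp.R`, to reproduce the benchmark's study
conditions:

* **Scenario 1** ("correct specification"): main-terms propensity model;
  outcome model with a strong `w2:w4` term; severity 1 (propensity 1st
  percentile ≈ 0.027 — visible near-positivity, mild enough that
  correctly specified weighting estimators stay nearly unbiased). The
  treatment coefficient of the outcome model is root-found by
  deterministic quadrature so that $\psi_0 = -0.1813$ exactly. A
  main-terms naive fit overestimates the effect magnitude by roughly a
  quarter under these conditions.
* **Scenario 2** ("dual misspecification"): the age score widens to
  uniform$(-1, 1)$ and the age-by-comorbidity interaction enters *both*
  models — as the `w2:w4` product plus a moderate nonlinear component
  `w2^2:w4` that lies outside the span of order-2 polynomial candidates
  and learners; the near-positivity tail is deeper (severity 1.25, 1st
  percentile of $g_0$ near 0.003). The treatment coefficient is
  root-found so that $\psi_0 = -0.1172$. Under these conditions a
  main-terms naive fit collapses towards zero (relative bias around
  90–110%); the data-adaptive strategies recover the `w2:w4` product and
  repair most of the bias, but the irreducible residual misspecification
  interacts with the extreme unbounded weights: the best-fit AIPTW
  estimator keeps a double-digit relative bias, while TMLE (bounded
  propensities, substitution form) and IPTW-RA (weights enter only the
  regression fit) stay within a few percent — the regime the benchmark is
  designed to exhibit.

Because the true ATE depends only on the outcome model, the severity knob
can be moved without re-calibration.

What the generator does *not* emulate: real registries have correlated,
partly categorical covariates, measurement error, informative
missingness, and joint stage-by-presentation structure. Passing the
benchmark shows correct estimator behaviour under the stated structural
model, not performance on any particular registry.

### The lung-cohort emulator

`generate_lung_cohort()` produces a synthetic cohort shaped like an
English lung-cancer registry extract: sex-specific sizes (80,891 women,
102,535 men by default), normally distributed ages (means 73.0/72.6,
SDs 10.8/10.3 years), an emergency-presentation exposure, stage I–IV,
and a 1-year death indicator drawn from conditional mortality
proportions: 53.4%/83.7% (women, non-ER/ER) and 59.9%/86.4% (men). The
sex-by-ER and sex-by-stage mortality tables are calibration inputs; the
*joint* law of ER status and stage is not modelled (it is not published),
so death is drawn from one table at a time (`calibrate_by`). ER
prevalence (0.35) and the stage distribution (15/10/25/50%) are synthetic
defaults chosen as realistic for lung cancer; they are not calibration
targets. `lung_benchmark()` runs a fixed-covariate Monte Carlo on this
cohort — covariates drawn once, exposure and outcome re-simulated each
replication — as a structurally analogous, clearly synthetic counterpart
of a registry-based simulation.

## The Monte Carlo harness

`run_monte_carlo()` draws `reps` cohorts (each from a sub-seed derived
deterministically from the master seed, so any replication is re-runnable
in isolation), applies every configured estimator, and aggregates:

* mean and SD of the estimates across replications,
* absolute bias $|\bar\psi - \psi_0|$ and relative bias
  $100\,|\bar\psi - \psi_0| / |\psi_0|$,
* $\text{RMSE} = \sqrt{\text{mean}((\hat\psi_r - \psi_0)^2)}$,
* 95% CI coverage of $\psi_0$.

The truth $\psi_0$ is computed by the plug-in method: average of
$Q_0(1, W) - Q_0(0, W)$ over $10^6$ covariate draws, so its Monte Carlo
error is of order $10^{-4}$. Estimator failures inside a replication
(positivity errors, non-convergence, empty arms) are caught per
estimator, logged, and excluded from the metrics with their count
reported; an estimator failing in more than 20% of replications is
flagged unreliable rather than imputed.

Two profiles are provided: `"full"` (1,000 replications, 10-fold super
learner — the benchmark's original design) and `"scaled"` (200
replications, 5-fold), the desk-scale profile used by the package's own
acceptance runs; the vignette and test suite use the scaled sizes.

## Numerical choices

* **Logistic fits** use a matrix-interface Newton/IRLS solver (compiled
  core) with step-halving, at most 100 iterations and tolerance $10^{-8}$
  on the largest coefficient change. Perfect separation is reported
  (`converged = FALSE`, with a warning), never penalised away; aliased
  columns are dropped via pivoted QR with `NA` coefficients, mirroring
  `glm`. The fitter is cross-checked against `stats::glm.fit` in the test
  suite.
* **Fluctuation step**: two-parameter targeting in $(H_1, H_0)$ by
  default (a single-$\varepsilon$ variant is switchable), 50 iterations,
  tolerance $10^{-10}$; $\bar Q$ and $g$ are truncated to
  $[10^{-6}, 1 - 10^{-6}]$ before logit transforms.
* **Weight tolerances**: AIPTW and IPTW-RA refuse fitted propensities
  within `ps_tol` of 0 or 1 (default $10^{-5}$) with an error naming the
  offending count; the scenario-2 roster relaxes AIPTW's tolerance to
  $10^{-8}$, the escape hatch needed to push the estimator through severe
  near-violations. TMLE instead bounds $g$ to $[0.025, 0.975]$.
* **CIs** use the normal multiplier 1.96 throughout.
* **Influence-curve SEs** use the $n-1$ sample variance,
  $\widehat{\text{se}} = \sqrt{\widehat{\text{Var}}(IC)/n}$.

## A small worked run

A deliberately small run (desk scale, a few seconds):

```{r example}
res <- run_scenario(
  scenario = 1, n = 500, reps = 20, seed = 42,
  estimators = c("naive", "aiptw", "tmle")
)
tidy(res)
```

The qualitative pattern of the full benchmark is already visible: the
naive estimator overshoots the true risk difference while the
double-robust estimators centre on it. `autoplot(res)` draws the
sampling distributions; `report_table(res)` formats the benchmark table.

## Known limitations

* The naive estimator's exact construction in the original benchmark is
  unpublished; the linear-probability-coefficient reading is the one
  whose bias behaviour matches the reported pattern, and it is the
  package's documented choice.
* Inference treats replications and subjects as i.i.d.; clustered
  designs, time-to-event outcomes and ratio effect measures are out of
  scope.
* The AIC/BIC selector reports, but does not adjudicate, AIC–BIC
  disagreement; selection is by a single configured criterion.
* Super-learner and best-fit nuisance estimates are data-adaptive, and
  the reported influence-curve standard errors do not account for the
  model-selection step itself — the usual caveat for these estimators.
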