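---
title: "Handling partially observed time-varying confounders in marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling partially observed time-varying confounders in marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal observational studies of a time-varying binary treatment
$A_k$ ($k = 0, \dots, K-1$) routinely exhibit *treatment–confounder
feedback*: earlier treatment changes later confounder values, which in turn
drive later treatment decisions.  Conditioning on such confounders in an
outcome regression blocks part of the treatment effect (they are mediators
of earlier treatment), while ignoring them leaves confounding.  Marginal
structural models (MSMs) resolve this by weighting.  For an end-of-study
continuous outcome $Y$ the package targets the additive MSM

$$ E[Y^{\bar a}] = \beta_{\mathrm{int}} + \beta_0 a_0 + \beta_1 a_1 + \cdots
   + \beta_{K-1} a_{K-1}, $$

whose coefficients contrast counterfactual outcome means under static
treatment regimes $\bar a \in \{0,1\}^K$.  Estimation proceeds in two
stages: pooled logistic regression over person-time rows gives each
subject's probability of the treatment actually received at each visit
(denominator), a treatment-history-only model gives the stabilization
numerator, and the cumulative products of their ratios weight an ordinary
least-squares regression of $Y$ on treatment history.  The default variance
is the heteroskedasticity-robust sandwich with weights treated as known —
conservative, because it ignores weight-estimation uncertainty; a
subject-level nonparametric bootstrap that refits the whole pipeline inside
each resample is available as the corrective option.

When the time-varying confounders $L_1$ (binary) and $L_2$ (continuous) are
incompletely recorded, five strategies are implemented, each ending in the
same weighted MSM fit:

* **complete case (CC)** — drop any subject with a missing confounder cell;
* **last observation carried forward (LOCF)** — forward-fill each
  confounder from its most recent observed value, dropping subjects with
  missing baselines;
* **missingness pattern approach (MPA)** — partition person-time rows at
  each visit by which confounders are missing, and fit the denominator
  model within each pattern from its observed covariates only;
* **multiple imputation (MI)** — chained-equation imputation conditioning
  on the outcome, all treatments and all confounder columns, analyzed per
  completed data set and pooled by Rubin's rules
  ($T = W + (1 + 1/M)B$);
* **inverse-probability-of-missingness weighting (IPMW)** — monotonize
  missingness by censoring each subject at their first incomplete visit,
  estimate stabilized remain-probability weights by pooled logistic
  regression, and multiply them into the treatment weights.

## What the generator emulates

`dgm_config()` encodes a sequential structural model chosen to mimic a
registry-style cohort: a baseline risk factor $V \sim N(0,1)$ affecting only
the outcome; a binary confounder $L_{1}$ (an episodic symptom; weak
autoregression, logit slope 0.3 on its previous value); a continuous
confounder $L_{2}$ (a fast-turning standardized biomarker; autoregression
0.4, innovation SD 0.9); treatment feedback into both confounders (+0.6 per
dynamics equation); a treatment model with log-odds slopes 0.7 on each
current confounder (odds ratios near 2, i.e. moderate-to-strong
confounding) and 0.4 on the previous treatment; and an outcome combining
direct treatment effects of 0.4 per visit with confounder effects of 0.6
per visit, $0.8V$, and unit Gaussian noise.  With probability 0.3 per visit
each confounder *repeats its previous value exactly* ("sticky" carry-over —
the measurement was taken but nothing changed), which makes the
constant-value missingness mechanism well defined for the continuous
confounder.

The coefficients were fixed once, before any estimator comparison, with two
declared calibration goals: (i) confounding strong enough that the
method-by-mechanism combinations known to be invalid display bias several
Monte-Carlo standard errors wide at the replication scales used in the test
suite, and (ii) value repeats under the constant mechanism close to
exogenous (hence the weak $L_1$ autoregression centred at probability one
half), so that complete-case selection on repeat status stays mild, as
reported for that mechanism.

Six missingness mechanisms overlay the complete panels.  MCAR, the three
MAR variants and the differential mechanism draw **one record-level
indicator per subject-visit** — the single $R_k$ node of the corresponding
causal graph — masking both confounders at that visit; the constant
mechanism is per variable because each value's own repeat status determines
its missingness.  This choice matters for IPMW: with a record-level
indicator the pooled logistic remain-model is correctly specified, whereas
with independent per-variable masking the probability of a fully observed
visit is $(1-p)^2$, which is not logistic in the predictors, and IPMW
acquired a visible structural bias in its own validity cells when we tried
that variant.  History-dependent mechanisms start at $k = 1$ (their
predictors are lagged); only MCAR masks baseline values.  Under the
differential mechanism the per-visit generation order becomes
$L_k \to R_k \to A_k$ and the treatment model simply drops a masked
confounder — the physician cannot act on a value they never saw — so the
panel's treatments (and everything downstream) are re-drawn; this is the
one documented exception to the contract that masking never alters true
values.

Calibration of each mechanism's intercept to the target missingness level
(40% main, 5% secondary, measured over the cells the mechanism may mask) is
monotone root finding against a fixed 20,000-subject calibration panel;
for MCAR the intercept is `qlogis(target)` analytically.

What the generator does **not** emulate: sparse or asynchronous visit
schedules (missingness here means an unrecorded value at a held visit),
missing treatment or outcome data, repeated outcome measurement, binary or
survival outcomes, and more than two confounders.  Passing tests therefore
demonstrate correctness of the estimators under this stylized registry
world, not robustness to every feature of real electronic health records.

## The truth oracle

The estimand is defined as the least-squares projection of the $2^K$
counterfactual regime means onto the additive MSM surface with equal regime
weights.  `true_msm_coefficients()` computes it two ways: a Monte-Carlo
g-formula (simulate forward with treatment hard-set; confounder dynamics
still respond) and, for the all-linear-Gaussian variant
(`dgm_config_linear()`), exact mean propagation through the structural
equations.  With the default configuration the additive surface holds to
within Monte-Carlo error (the projection residuals are reported as
`additivity_gap`), because the only nonlinearity — the logistic $L_1$
dynamics — contributes an interaction far below the resolution of the
simulations; the two oracles agree within three Monte-Carlo standard errors
on the linear variant, which is verified in the test suite rather than
assumed.

## Numerical and design choices

* **Weight models.**  Time-specific intercepts with slopes shared across
  visits in both the numerator and denominator, matching the generating
  treatment process.  Weight truncation is off by default (symmetric
  percentile truncation is available).  $A_{-1} = 0$ by convention.
* **MPA numerator.**  The denominator is pattern-specific but the numerator
  is a single pooled model in past treatment.  A pattern-specific numerator
  conditions the stabilized weights on pattern membership — a descendant of
  earlier confounders that is not in the marginal model — and in probe
  simulations this produced a clear bias precisely in the differential
  scenario the MPA is meant to handle; the pooled numerator removed it.
  Patterns with fewer than 50 person-time rows are merged into the nearest
  coarser pattern (one more covariate dropped from their model).
* **MI engine.**  Five chained-equation cycles per imputation (the
  convention of mainstream imputation software; doubling the cycle count
  produced no visible drift in probe runs), $M = 10$ imputations by
  default, visit order of increasing missingness, predictive mean matching
  with 5 donors for continuous columns, logistic draws for binary columns,
  and approximate-Bayesian parameter draws (normal coefficient draw around
  the MLE, scaled chi-square draw for the residual variance) so
  between-imputation variance is properly generated.
* **IPMW.**  Censoring at the first incomplete visit (monotonization), so a
  subject observed again later still contributes nothing after censoring.
  Visits at which nobody is censored get remain-probability 1 rather than
  entering the fit.
* **Degenerate inputs.**  Saturated or separated weight models, empty
  complete-case sets, all-missing columns, non-binary treatments and
  mis-specified schemas raise typed conditions (`msmiss_*_error`), which the
  command-line interface maps to exit codes (1 analysis, 2 usage).
* **Seeding.**  Every stochastic stage derives independent substreams from
  one root seed (`substream_seed()`), keyed by stage and replicate index, so
  scenario results are invariant to execution order and exactly
  reproducible.

## Scale of the shipped simulations

The test suite reproduces the method-by-mechanism validity grid at
deliberately economical scales — e.g. full-data recovery at $n = 10{,}000$
with $R = 200$ replicates, cheap-method grids at $n = 10{,}000$–$20{,}000$
with $R = 50$–$200$, and MI cells at $n = 5{,}000$–$8{,}000$ with $R = 40$ —
chosen so each run resolves the biases it asserts (unbiased cells within
three Monte-Carlo SEs, invalid cells beyond five) while the whole suite
stays comfortably runnable on a laptop.  The orchestrator defaults to
$R = 1{,}000$ for full study-size runs.

## Known limitations

The sandwich variance understates uncertainty in the weights (coverage in
the grid runs is often above nominal for that reason); the bootstrap is the
remedy but is too expensive inside large grids.  LOCF's reported standard
error ignores its single-imputation uncertainty by construction.  The MPA
is limited to confounder missingness and coarse per-visit patterns; with
many confounders its patterns would thin out quickly.  Under the
differential mechanism we sever only the contemporaneous edge from a masked
confounder to treatment; whether carried-forward information should also
sever later edges is a modeling choice we did not take.
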