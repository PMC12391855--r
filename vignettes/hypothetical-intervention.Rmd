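---
title: "Estimating how early pregnancy recognition would reduce inequalities in antenatal care timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating how early pregnancy recognition would reduce inequalities in antenatal care timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Gestational age at the first antenatal care visit (the outcome $Y$, in
weeks) differs systematically across social groups: younger pregnant people,
migrants, those with unplanned pregnancies, lower education, lower household
income, unemployment, rented housing, deprived neighbourhoods, limited
language skills and lower cognitive functioning all tend to start care
later. Most of these predictors cannot be intervened on. Recognising the
pregnancy early — within 6 weeks of the first day of the last menstrual
period (the binary exposure $A$) — can be. This package estimates, for each
predictor level $l$ versus a reference level, the inequality in initiation
timing as it stands, the inequality in the counterfactual scenario where
*everyone* recognises the pregnancy early (`do(A = 1)`), and the difference
between the two: the **reduction** attributable to the hypothetical
intervention.

## Model and estimands

Per predictor, the *inequality without intervention* is the coefficient of a
one-predictor-at-a-time OLS regression of $Y$ on level indicators — i.e. the
difference in group means, in weeks, versus the reference level. Following
the design of the analysis this package implements, the reference is chosen
empirically as the level with the *earliest* mean initiation, so inequalities
are positive; the choice is frozen on the observed data and reused for the
counterfactual scenario. These one-at-a-time regressions are deliberately
unadjusted: they describe the disparities as they exist, not any causal
pathway (an `adjusted = TRUE` switch fits the mutually adjusted variant).

The exposure effect is estimated from the adjusted model
$$
Y_i = \beta_0 + \beta_A A_i + \sum_p \beta_p^\top X_{ip} + \varepsilon_i,
$$
with main effects for all 13 predictors as the confounder adjustment set.
Counterfactual outcomes are built by the outcome-shift construction
$Y^*_i = Y_i + \hat\beta_A (1 - A_i)$: exposed participants keep their
observed outcome exactly (consistency), and for a main-effects linear model
the shift is algebraically identical to model-based prediction under
`do(A = 1)` plus the participant's residual, which `method = "predict"`
computes explicitly and which also supports exposure–covariate interactions.
Re-running the inequality regressions on $Y^*$ gives the *with-intervention*
column, and the reduction for level $l$ obeys the closed form
$$
\mathrm{reduction}_l = \hat\beta_A (\bar A_{\mathrm{ref}} - \bar A_l):
$$
an inequality shrinks exactly insofar as the disadvantaged level lags the
reference in early-recognition prevalence. This identity (checked to
$10^{-8}$ in the test suite) is also the main interpretive device: with
$\hat\beta_A < 0$ and prevalence gaps below 1, no reduction can exceed
$|\hat\beta_A|$ in magnitude.

Identification rests on the usual trio: *exchangeability* (no unmeasured
confounding given the 13 predictors), *positivity* (every covariate pattern
retains a non-zero probability of early recognition — diagnosed by
`check_positivity()`, which reports the minimum fitted propensity score on
complete cases of the non-imputed data and warns below a configurable floor
of 0.01), and *consistency* (the intervention is well defined — probed by
re-running the whole pipeline on the regular-cycle subset via
`filter_regular_cycle()`, the group for which "test when your period is
late" is a meaningful instruction).

`standardization_oracle()` provides an independent check of the g-computation
machinery: on small tables it computes the counterfactual by exhaustive
stratum-wise substitution of the exposed-stratum mean outcome, which must
agree with `estimate_reduction()` exactly when the outcome model is
saturated. The test suite verifies this on 200 randomised tables.

## The synthetic cohort generator

The real cohort is confidential, so `generate_cohort()` is a first-class
module that emulates the analytical sample's published structure, and its
defaults (from `default_params()`) *are* the study conditions:

* **Size and marginals.** $n = 4196$; each categorical predictor is drawn
  from the published per-level proportions stored in
  `calibration_counts()`. Parity proportions were not published; the default
  (0.55/0.30/0.10/0.05 for 0/1/2/3+ children) is a realistic primiparous-
  majority mix for an urban birth cohort.
* **Joint structure.** Only the margins are published, so predictors are
  drawn independently (the documented copula choice). Dependence between
  the exposure and its confounders is created explicitly: $A$ follows a
  logistic model on education, income, age group and pregnancy intention —
  the steepest published gradients — with the intercept solved numerically
  so the marginal prevalence is exactly 0.817. The default coefficients
  span stratum probabilities of roughly 0.55–0.89, keeping propensities far
  from 0 and 1 (positivity by construction) while making the unadjusted and
  adjusted exposure effects visibly different.
* **Recognition timing.** Given early recognition, timing is a scaled
  Beta(2.7, 1.3) on [2, 6] weeks (mean 4.7); given late recognition, 6 weeks
  plus a Gamma whose two moments are solved so that the mixture reproduces
  the published overall mean 5.4 and SD 2.3 exactly. A uniform early
  component was considered and rejected: with an early mean of 4 weeks the
  late mean must be 11.65 weeks and the between-component variance alone
  already exceeds $2.3^2$, so no late distribution can match the printed
  moments.
* **Outcome.** $Y$ is linear in the predictors with coefficients following
  the published inequality ordering, plus $\beta_A = -0.6$ weeks (the
  published adjusted estimate) and Gaussian noise, truncated below at 4
  weeks (a first visit before ~4 gestational weeks is biologically
  implausible; the truncation affects under 1% of draws). Intercept and
  noise SD are solved so the marginal mean and SD are 12.9 and 3.7 weeks,
  accounting analytically for the exposure–confounder covariance. Gaussian
  noise cannot also reproduce the published 81.4% share of first visits at
  ≤ 14 weeks — that share reflects right-skewness the model does not carry —
  so the synthetic timely share is ~62%. Tests about the ≤ 14-week
  dichotomisation therefore use the printed counts, not generated data.
* **Missingness.** Per-variable rates are derived from the published count
  shortfalls (1.1%–36.2% across predictors, 25.5% for recognition timing).
  Cells are blanked MAR: the log-odds of missingness are shifted for low
  education and first-generation migration, and — for recognition timing —
  by +3.0 for participants initiating care after 14 weeks (`init_weeks` is
  always observed, so this is strictly MAR). The late-initiation driver
  matters: education/migration gradients alone move the complete-case
  early-recognition prevalence by under 0.1 percentage points, which would
  make complete-case analysis indistinguishable from imputation; with it,
  the complete-case bias is a detectable ~1.2 points that chained imputation
  must (and does) remove. Each variable's missingness intercept is solved on
  the realised cohort so the marginal rate is hit exactly in expectation.
  Education and migration themselves are blanked completely at random.

What passing tests on this generator do *not* show: robustness to
correlated predictors, to skewed outcomes, to informative (MNAR)
missingness, or to exposure models outside the logistic family. They show
that the estimation machinery recovers known truths under the assumptions
the method itself states.

## Chained imputation

No imputation engine is assumed from the environment; `impute_chained()` is
a complete implementation of multiple imputation by chained equations:

* Variables are visited in ascending order of missing fraction
  (alphabetical within ties). Initial values are draws from each variable's
  observed marginal; with the generator's shallow conditional structure
  (independent covariates, a single outcome link), the chain settles within
  one or two sweeps, which `plot_imputation_trace()` makes visible. The
  package default is the study configuration (50 datasets, 100 iterations);
  the test suite uses 2–10 datasets and 2 iterations, problem sizes chosen
  to keep full-pipeline tests in minutes while leaving every estimand
  within Monte-Carlo tolerance of its target.
* Continuous variables use predictive mean matching (type-1: Bayesian
  parameter draw for the missing rows' predictions, 5 donors, imputes real
  observed values — so imputations respect ranges and granularity). Binary
  variables use logistic posterior draws; factors with 3+ levels use a
  baseline-category multinomial logistic fitted by ridge-stabilised chord
  iterations (the Hessian is factorised once per fit and refreshed every
  fourth step, with coefficients warm-started across sweeps — an exact MLE
  at a fraction of full-Newton cost). Non-convergent fits fall back to
  marginal draws and are recorded in the object's log.
* The derived indicator `early_recognition` is handled by *passive
  imputation*: it is recomputed as `recognition_weeks <= 6` after every
  update of recognition timing, so the definitional invariant can never be
  violated. Before recognition timing is drawn, the indicator itself is
  imputed by a logistic draw given everything except its source variable.
  This matters for bias: under the Gaussian outcome model the true
  conditional of $A$ given outcome and covariates is exactly logistic, and
  including the drawn indicator in the PMM design for recognition timing
  splits the donor pool cleanly into early and late donors. Without this
  step the weak linear association between timing and outcome attenuates
  the pooled exposure effect by roughly 15%; with it, recovery is unbiased
  to Monte-Carlo precision (the 100-replication test).
* The three auxiliaries (BMI at intake, gestational age at intake, 5-minute
  Apgar) enter every conditional model, as auxiliaries should: they carry
  information about the incomplete variables without entering the analysis
  model.

Pooling follows Rubin's rules (`pool_rubin()`): mean estimate, within plus
$(1 + 1/m)$ between variance, t-intervals with Barnard–Rubin degrees of
freedom (reducing to the classic large-sample value when the complete-data
degrees of freedom are left infinite).

## Uncertainty

Confidence intervals are percentile-bootstrap (the plain percentile
variant; nothing in the analysis justifies BCa's extra machinery), combined
with multiple imputation in the *bootstrap-after-imputation* ordering: the
expensive imputation is done once; each of the $B$ replicates draws one row
resample and applies the same indices to every imputed dataset, keeping
within-person correlation intact. Re-imputing inside every replicate would
cost $m \times B$ imputation runs and is out of reach at the study
configuration.

One design point deserves emphasis. Averaging the $m$ per-imputation
estimates into a single number per replicate and taking percentiles over
those $B$ means looks natural but *undercovers*: the averaging shrinks the
imputation-noise component by $1/m$, while a valid total variance requires
inflating the between-imputation component by $(1 + 1/m)$. Measured on the
null configuration, that variant's replicate SD was 0.095 weeks against a
true sampling SD of ~0.15 for the pooled exposure effect. The package
therefore takes percentiles over the pooled bootstrap sample of all
$m \times B$ per-imputation estimates, whose spread carries both the
row-sampling and the between-imputation variability and closely matches the
Rubin-rule total variance. Point estimates always come from the unresampled
data. Reduction intervals are computed on reduction draws themselves (the
difference is taken inside each draw, never between interval endpoints).
Draws in which a predictor level vanishes from the resample are recorded
absent; parameters with more than 1% absent draws are flagged in the
report.

## Numerical choices and degenerate inputs

* OLS fits go through R's rank-revealing QR (`lm`/`lm.fit`); indicator
  columns emptied by subsetting are dropped and recorded, never silently
  zeroed. Imputation-model fits add a ridge of $10^{-6}$ times the mean
  Hessian diagonal, which regularises separation and collinearity without
  measurably moving interior solutions; Newton steps are clamped to ±4 on
  the linear-predictor scale.
* Reference-level ties break by dictionary order; empty levels are excluded
  from candidacy with a warning.
* The 6- and 14-week dichotomisation boundaries are inclusive (≤), matching
  the convention of the descriptive table they reproduce; both are
  arguments, not constants.
* Percentile intervals use the linear-interpolation quantile (type 7),
  which is exactly the rank-interpolation formula documented in
  `percentile_ci()`.
* Degenerate cases are defined, not accidental: zero missingness returns
  $m$ identical copies; a constant bootstrap statistic returns a degenerate
  interval; a noiseless flat outcome model returns a constant cohort; a
  fully missing variable, a missingness rate on the outcome, and a
  perfectly separated propensity model are errors naming the offending
  variable.

## Reproducibility

Every stochastic step takes an explicit integer seed, and
`run_full_analysis()` derives all module seeds (generation, blanking,
imputation, bootstrap) from one master seed, so a configuration reproduces
its report byte-for-byte (timestamps aside). The run manifest records the
seeds, a configuration hash and the package version.

## Known limitations

* The generator's independence copula understates real-world predictor
  clustering; in particular, complete cases are rarer than in a cohort with
  correlated missingness, so the complete-case propensity diagnostic is fit
  on few rows at realistic rates (it errors informatively on separation,
  and the pipeline records that instead of failing the run).
* The outcome-shift counterfactual presumes a homogeneous exposure effect;
  effect modification requires `method = "predict"` with an interaction
  model, for which the closed-form reduction identity no longer holds.
* Bootstrap-after-imputation treats imputed values as data within each
  replicate; its pooled-sample intervals are approximately, not exactly,
  calibrated (the null-configuration replication study in the test suite
  quantifies this).
* With a positive-skew-free Gaussian outcome the synthetic timely-initiation
  share cannot match the published one; analyses of the ≤ 14-week indicator
  on synthetic data describe the generator, not the published cohort.
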