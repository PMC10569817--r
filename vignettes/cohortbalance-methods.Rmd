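---
title: "Distribution-matched undersampling and risk-factor importance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-matched undersampling and risk-factor importance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large prevention-trial cohorts that record a binary disease outcome are
almost always heavily imbalanced: the non-event (majority) class can hold
more than 90% of the records. A logistic regression fitted to such data and
thresholded at 0.5 converges to a classifier that predicts the majority
class for everyone — accuracy looks excellent, sensitivity is zero,
precision is undefined — and the fit carries almost no usable information
about how the predictors relate to the event. `cohortbalance` implements a
three-step remedy:

1. **Balance** the classes by undersampling the majority class with a
   *distribution-matched* subsample (or, for comparison, oversampling the
   minority with SMOTE).
2. **Fit** a binary logistic regression on the balanced data and read off
   clinical performance metrics, two-proportion contrasts and joint Wald
   tests.
3. **Rank** predictors by the flatness of their partial-dependence curves.

Everything operates on a `cohort` object — a rectangular record table plus a
declared variable schema (kinds, levels, roles, threshold-derived
indicators) — so that categorical levels are validated at load time and the
event level is unambiguous (it is always the second declared outcome level).

## Step 1: best-of-M distribution-matched undersampling

A plain random undersample of the majority class equalizes the classes but
may, by chance, distort the majority's covariate distributions. The method
here draws `m` independent candidate subsamples (default `m = 1000`, each of
size n_minority, without replacement), scores each candidate against the
*whole* majority class variable by variable, and keeps the candidate with
the highest summed p-value:

* **categorical variables** — chi-squared goodness-of-fit of the candidate's
  level counts against the majority population's level proportions
  (via `chisq.test`; a population level with zero members has zero expected
  count and is dropped from the table, and a variable left with fewer than
  two populated levels is uninformative and scores p = 1);
* **continuous variables** — two-sample Kolmogorov–Smirnov test of the
  candidate against the majority population. The statistic is the maximum
  absolute ECDF difference with the ECDF stepping at every observed value
  (which is also the tie convention; ties are guaranteed here because the
  candidate is a subset of the population). The p-value is the asymptotic
  Kolmogorov tail, evaluated with the exact series (Jacobi-theta form below
  t = 1, alternating form above), so it is accurate to machine precision
  rather than to a fixed truncation tolerance.

The score is the unweighted sum of the p-values — no weighting, no Fisher
combination — so a candidate indistinguishable from the population on every
scored variable scores close to the number of variables. Age and BMI are
scored in their continuous form by default; their threshold-derived
indicators (`age_gt65`, `bmi_gt25`) are excluded from default scoring to
avoid double-counting, though any variable list can be passed explicitly.

Two determinism rules matter. All `m` candidates are drawn up front from a
single generator seeded once per call, so candidate *c* is always the *c*-th
draw and the result cannot depend on the order in which candidates are
scored. Score ties are broken in favour of the earliest-drawn candidate.
Identical `(cohort, m, seed)` therefore reproduce the result bit-exactly.

### The stratified variant

To control chosen confounders (typically an age indicator and sex), the
stratified sampler fixes per-stratum quotas: within every cell of the cross
of the stratum variables it draws exactly as many majority rows as the
minority class has there, so the sampled majority's joint stratum
distribution equals the *minority's* exactly (that is the stated goal of the
design — matching the event class's age/sex composition). Candidates are
drawn jointly — one candidate consists of one quota-draw in every stratum —
and best-of-`m` selection proceeds as above, scoring only non-stratum
variables; the stratum variables, and the continuous sources of
threshold-derived stratum indicators, are matched by construction and would
only dilute the score. A minority stratum with too few majority rows is an
error that names the stratum.

### SMOTE, for comparison

The in-package SMOTE implementation generates n_majority − n_minority
synthetic minority rows. Features are encoded numerically (continuous
predictors as-is, categorical predictors as 0/1 indicators, threshold
duplicates excluded) and standardized by the pooled mean/SD; each synthetic
row is a uniform convex combination of a random minority seed row and one of
its k nearest minority neighbours (Euclidean distance in the standardized
space, `k = 5` by default, the original technique's convention). Mapping the
point back to a record rounds each indicator to {0, 1}, which is equivalent
to keeping the dominant parent's level (interpolation weight λ ≤ 0.5 keeps
the seed row's level); threshold indicators are recomputed from the
interpolated continuous sources so the derived columns stay consistent. The
result records every synthetic row's parent pair, weight and pre-rounding
coordinates, so the convex-combination geometry can be verified exactly.

## Step 2: logistic regression and clinical metrics

`fit_logistic()` is a thin, opinionated layer over `stats::glm(binomial)`:
treatment (reference-level) coding with the reference defaulting to each
factor's most frequent level (configurable — analyses that want specific
clinical baselines such as male / age ≤ 65 / non-smoking pass
`reference_levels` explicitly, and the worked examples do); the reported AIC,
BIC and deviance satisfy the identities AIC = −2ℓ + 2k, BIC = −2ℓ + k·ln n,
deviance = −2ℓ (exact for ungrouped binary data). Quasi-complete separation
is detected (|coefficient| > 10 with SE > 50) and refused by name rather than
silently regularized; the pipeline relaxes this to a warning so that sparse
subgroup fits can still be reported as-is, degenerate coefficient included,
the way reference analyses print them. No penalized fallback is provided.

`confusion_metrics()` flags precision and NPV as *undefined* (not 0) when
their denominators are empty — precisely the signature of the all-negative
classifier the imbalanced fit produces. `two_proportion_test()` uses the
Wald interval without continuity correction and the Pearson chi-squared
statistic on the 2×2 table (df = 1); the interval style for the published
contrasts is unstated, and Wald-without-correction is the conventional
default of `prop.test`-like output, so that is the documented assumption.
`wald_factor_test()` tests a factor's L−1 coefficients jointly with
W = bᵀV⁻¹b, df = L−1.

A useful sanity property connects the balanced fit to the full-data truth:
undersampling the controls at sampling fraction f is case–control sampling,
so slopes are unchanged while the intercept shifts by −ln f = ln(n_maj /
n_min). The tests verify both halves on generated data.

Performance metrics are computed in-sample on the balanced set by default
(matching our reading of how the reference performance tables were
produced); an optional class-stratified holdout split (`holdout_fraction`)
is provided because an independent validation set is mentioned in the
source analyses without being described. Neither mode is asserted as "the"
published protocol.

## Step 3: PDP-flatness importance

The partial dependence of the fitted model on a variable is the mean fitted
event probability over all rows after overwriting that variable with each
grid value — the response scale, not the link scale, because the flatness
interpretation concerns the predicted probability. Continuous grids use 20
equally spaced quantiles of the observed values (grid size and scale are
design choices surfaced as arguments); categorical grids enumerate levels.
The importance score is the sample SD of the curve for continuous
variables and (max − min)/4 for categorical ones — the range/4 convention
that puts a two-level factor on a comparable scale. A flat curve means the
variable does not move the model's average prediction: score 0. Variables
absent from the model score exactly 0, and ranking ties break
alphabetically.

## The synthetic cohort generator

Because the motivating trial data are access-restricted, the generator
builds cohorts with the same shape and known ground truth: ~25,000 records;
race drawn with probabilities proportional to (71, 20, 4)% over NHW, NHB
and Hispanic; sex, age, BMI and smoking drawn conditionally on race
(female 48/62/35%, smoking 5/14/6%, per-race normal age and BMI with the
published group means/SDs, truncated to [50, 100] years and [15, 60] kg/m²
via inverse-CDF sampling); a 50/50 treatment arm; and a Bernoulli outcome
with log-odds = intercept + 0.5·(age>65) − 0.43·female + 0.09·(BMI>25) −
0.05·(active arm) + 0.47·smoking − 0.44·NHB − 0.48·Hispanic. The intercept
is calibrated by bisection on a separately seeded 200,000-draw pilot so the
overall prevalence is 6.3%.

Two deliberate simplifications are worth knowing. First, covariates are
conditionally independent given race — only marginals and per-race
contrasts are published, so no covariance structure is imposed. Second, the
published per-race age moments and the published under-65 fractions are
mutually inconsistent under a normal model (the NHB mean/SD imply roughly
60% under 65, not the stated 70%); the defaults follow the printed per-race
moments, which reproduce the overall mean age (≈66.6) and BMI (≈28.1)
exactly, and accept approximate under-65 fractions. Consequently, passing
tests demonstrate that the pipeline recovers known effects under realistic
imbalance, prevalence and marginals — not that it reproduces any statistic
of the real trial data, whose correlations, skewness and missingness the
generator does not emulate.

## Numerical and design choices, collected

* Missing data: row-wise deletion only (`missing_policy = "drop_row"`), or
  refuse to load; no imputation. Categorical comparison is case-sensitive
  after trimming surrounding whitespace.
* Class tie (n_maj = n_min): the second-declared outcome level — the event —
  is reported as the minority.
* KS p-values: asymptotic two-sample formula; exact small-sample
  distributions are out of scope because candidate sizes are in the
  hundreds or thousands.
* Degenerate two-proportion input (pooled proportion 0 or 1): statistic 0,
  p = 1.
* Whether the original analysis scored age/BMI continuously or binarized in
  Step 1 is unstated; continuous is the default here (both are supported via
  the schema) because the distributional comparison is strictly more
  informative.
* Whether stratified candidates are drawn jointly or per stratum is
  unstated; they are drawn jointly with fixed per-stratum quotas, which
  keeps "one candidate = one complete subsample" and a single score per
  candidate.
* Per-group analyses filter the pooled balanced data by group by default
  (`rebalance_within_group = TRUE` re-balances inside each group instead).
* Pipeline artifacts are stamped with an MD5 hash of the canonical JSON
  serialization of the config plus all seeds, so reruns are byte-identical
  and provenance is replayable.

## Problem sizes used by the test-suite studies

The Monte-Carlo suites run at sizes chosen to make the sampling noise small
relative to the margins being asserted while keeping the studies quick to
repeat: slope-recovery and degenerate/recovered-sensitivity studies use 20
replicate cohorts of n = 30,000 with best-of-100 selection; ranking studies
use 20 cohorts of n = 10,000; marginal-agreement studies use 20 cohorts of
n = 16,000 (≈1,000 minority rows); oracle-agreement suites use 100 random
fixtures. The acceptance script reports the same quantities from 10
replicates per study.

## Known limitations

* No survival/time-to-event modelling, mortality endpoints, ROC/AUC,
  regularized or Bayesian variants, near-miss/Tomek undersampling, or
  cost-sensitive losses.
* The importance method compares predictors within one fitted model;
  it is not a causal decomposition, and separated or near-separated terms
  make both coefficients and PDPs untrustworthy (which is why separation is
  surfaced loudly).
* The asymptotic KS p-value is slightly conservative for very small
  candidate sizes (tens of rows); the intended regime is hundreds and up.
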