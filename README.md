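# cohortbalance

Ranking risk-factor importance in imbalanced binary-outcome cohort data.

## The problem

Clinical cohorts that record a rare binary outcome — say, a cancer
diagnosis over a five-year surveillance window, at ~6% prevalence — defeat
naive logistic-regression analysis. Fitted to the full data and thresholded
at 0.5, the model predicts "no event" for everyone: accuracy ≈ 0.94,
sensitivity = 0, specificity = 1, precision undefined. Such a fit says
nothing about which risk factors matter. `cohortbalance` implements a
three-step framework for this setting:

1. **Distribution-matched undersampling.** Draw M (default 1,000) random
   subsamples of the majority class, each of size n_minority; score each
   subsample against the whole majority class — a chi-squared
   goodness-of-fit p-value per categorical variable, a two-sample
   Kolmogorov–Smirnov p-value per continuous variable — and keep the
   subsample with the highest summed p-value,

   argmax over candidates S of Σ_v p_v(S, majority).

   A stratified variant fixes per-stratum quotas (e.g. age>65 × sex) so the
   sampled majority matches the minority's joint confounder distribution
   exactly. An in-package SMOTE oversampler (convex combinations of
   k-nearest minority neighbours) is provided for comparison.
2. **Logistic regression** on the balanced set, P(event) =
   logistic(β₀ + Σ βⱼ xⱼ), with clinical performance metrics
   (sensitivity/specificity/precision/NPV/accuracy, undefined cells flagged
   rather than zeroed), two-proportion tests with Wald CIs and Pearson χ²,
   and joint Wald tests for multi-level factors (df = L − 1).
3. **PDP-flatness importance.** Each predictor's partial-dependence curve
   (mean fitted probability as the predictor sweeps its grid) is reduced to
   a flatness score — SD over a 20-point quantile grid for continuous
   predictors, range/4 over levels for categorical ones — and predictors
   are ranked by descending score.

Because the motivating trial data are access-restricted, the package ships
a synthetic cohort generator with the same structure (~25k records, 6.3%
prevalence, race/sex/age/BMI/smoking/treatment-arm marginals of the
published cohort, known log-odds effects), so the whole pipeline is
testable against ground truth. See `vignettes/cohortbalance-methods.Rmd`
for the full method description and design decisions.

## Worked example

```r
library(cohortbalance)

cfg <- default_vital_like_config()
coh <- generate_cohort(cfg, n = 25000, seed = 1)
coh
#> cohort: 25000 records, 9 variables (synthetic seed=1)
#>   outcome 'cancer': 1600 Yes (minority) vs 23400 majority

refs <- list(age_gt65 = "No", sex = "M", bmi_gt25 = "No",
             vitD = "No", smoking = "No", race = "NHW")
preds <- c("age_gt65", "sex", "bmi_gt25", "vitD", "smoking", "race")

# Step 0 (what goes wrong): the imbalanced fit is a degenerate classifier
full <- fit_logistic(coh, preds, reference_levels = refs)
confusion_metrics(cohort_records(coh)$cancer, predict_classes(full, coh))
#> confusion: tp=0 fp=0 tn=23400 fn=1600 (event = 'Yes')
#>   sensitivity 0.000  specificity 1.000  precision undefined  NPV 0.936  accuracy 0.936

# Step 1: best-of-100 distribution-matched undersample
bal <- select_balanced_undersample(coh, m = 100, seed = 2)
bal
#> balance_result (plain): 3200 balanced rows, seed 2
#>   best of 100 candidates, summed p = 5.379
#>     age     bmi     sex    race smoking    vitD
#>  0.8141  0.8521  0.9560  0.9413  0.9520  0.8636

# Step 2: logistic regression on the balanced data
fit <- fit_logistic(bal$balanced, preds, reference_levels = refs)
fit
#> logistic_fit: P(cancer = Yes), n = 3200
#>              estimate     se     z        p
#> (Intercept)   -0.1124 0.1003 -1.12 2.62e-01
#> age_gt65Yes    0.6079 0.0780  7.79 6.44e-15
#> sexF          -0.5070 0.0735 -6.90 5.19e-12
#> bmi_gt25Yes    0.0037 0.0801  0.05 9.63e-01
#> vitDYes       -0.0036 0.0727 -0.05 9.60e-01
#> smokingYes     0.4833 0.1359  3.56 3.76e-04
#> raceNHB       -0.5040 0.1028 -4.90 9.56e-07
#> raceHispanic  -0.4241 0.1887 -2.25 2.46e-02
#> AIC 4281.5  BIC 4330.1  logLik -2132.8  deviance 4265.5

confusion_metrics(cohort_records(bal$balanced)$cancer,
                  predict_classes(fit, bal$balanced))
#> confusion: tp=744 fp=428 tn=1172 fn=856 (event = 'Yes')
#>   sensitivity 0.465  specificity 0.733  precision 0.635  NPV 0.578  accuracy 0.599

w <- wald_factor_test(fit, "race")   # joint test of the race contrasts
cat(sprintf("Wald race: chi2 = %.1f, df = %d, p = %.2g\n", w$chi2, w$df, w$p))
#> Wald race: chi2 = 27.4, df = 2, p = 1.1e-06

# Step 3: PDP-flatness importance
pdp_importance(fit, bal$balanced,
               variables = c("age_gt65", "sex", "bmi_gt25", "vitD", "smoking"))
#> PDP-flatness importance (descending):
#>   age_gt65       0.03658
#>   sex            0.03038
#>   smoking        0.02828
#>   bmi_gt25       0.00022
#>   vitD           0.00021
```

Reading the output: balancing moved sensitivity from 0 to 0.47 at the cost
of specificity (1 → 0.73); the slope estimates sit close to the generating
effects (0.5, −0.43, 0.09, −0.05, 0.47, −0.44, −0.48) — undersampling
shifts only the intercept, by ln(n_majority/n_minority); and the importance
ranking puts the age indicator, sex and smoking far above the treatment arm
and BMI, whose generated effects are an order of magnitude smaller.

The same analysis runs end to end from a YAML config via `run_pipeline()`,
or from a shell through the thin front end:

```sh
Rscript inst/cli/cohortbalance.R simulate --n 25000 --seed 1 --out cohort.csv --schema schema.yaml
Rscript inst/cli/cohortbalance.R balance  --data cohort.csv --schema schema.yaml --m 1000 --seed 2 --out balanced.csv
Rscript inst/cli/cohortbalance.R pipeline --config run.yaml --out-dir results/
```

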