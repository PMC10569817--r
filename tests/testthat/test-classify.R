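test_that("intercept-only fits recover logit of the event proportion", {
  coh <- toy_cohort(n = 50, n_events = 25, seed = 1)
  f <- fit_logistic(coh, character(0))
  expect_equal(unname(f$coefficients[["(Intercept)"]]), 0, tolerance = 1e-8)

  coh2 <- toy_cohort(n = 200, n_events = 60, seed = 2)
  f2 <- fit_logistic(coh2, character(0))
  expect_equal(unname(f2$coefficients[["(Intercept)"]]),
               log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("a single binary predictor recovers the 2x2 log odds ratio", {
  # cells: exposed-event a, exposed-nonevent b, unexposed-event c, unexposed d
  a <- 30; b <- 70; c <- 15; d <- 85
  sc <- cohort_schema(list(
    schema_variable("exp", "categorical", levels = c("No", "Yes"), role = "predictor"),
    schema_variable("y", "categorical", levels = c("No", "Yes"), role = "outcome")))
  df <- data.frame(exp = rep(c("Yes", "Yes", "No", "No"), c(a, b, c, d)),
                   y = rep(c("Yes", "No", "Yes", "No"), c(a, b, c, d)))
  f <- fit_logistic(cohort(df, sc), "exp", reference_levels = list(exp = "No"))
  expect_equal(unname(f$coefficients[["expYes"]]),
               log(a * d / (b * c)), tolerance = 1e-6)
  expect_equal(unname(f$coefficients[["(Intercept)"]]),
               log(c / d), tolerance = 1e-6)
})

test_that("information criteria and deviance identities hold on every fit", {
  for (s in 1:3) {
    coh <- toy_cohort(n = 150, n_events = 40, seed = s)
    f <- fit_logistic(coh, c("age", "sex", "smoking"))
    k <- length(f$coefficients)
    expect_equal(f$aic, -2 * f$loglik + 2 * k, tolerance = 1e-8)
    expect_equal(f$bic, -2 * f$loglik + log(f$n_obs) * k, tolerance = 1e-8)
    expect_equal(f$deviance, -2 * f$loglik, tolerance = 1e-8)
    # treatment coding: an L-level factor contributes L-1 terms
    expect_equal(k, 1L + 1L + 1L + 1L)
  }
})

test_that("reference levels default to the most frequent level and are configurable", {
  coh <- toy_cohort(n = 300, n_events = 60, seed = 9)
  f <- fit_logistic(coh, "smoking")
  expect_equal(f$reference_levels$smoking, "No")  # 80/20 draw
  f2 <- fit_logistic(coh, "smoking", reference_levels = list(smoking = "Yes"))
  expect_equal(f2$reference_levels$smoking, "Yes")
  expect_equal(unname(f$coefficients[["smokingYes"]]),
               -unname(f2$coefficients[["smokingNo"]]), tolerance = 1e-8)
})

test_that("constant predictors and separated terms are refused by name", {
  coh <- toy_cohort(n = 80, n_events = 20, seed = 3)
  coh$records$smoking <- factor("No", levels = c("No", "Yes"))
  expect_error(fit_logistic(coh, "smoking"), "constant")

  # perfectly separating indicator
  df <- cohort_records(toy_cohort(n = 120, n_events = 30, seed = 4))
  df$smoking <- ifelse(df$cancer == "Yes", "Yes", "No")
  coh2 <- cohort(df, toy_schema())
  expect_error(fit_logistic(coh2, "smoking"), "separation.*smoking")
  expect_warning(fit_logistic(coh2, "smoking", on_separation = "warn"),
                 "separation")
})

test_that("predicted labels follow hand-computed logistic probabilities", {
  coh <- toy_cohort(n = 20, n_events = 8, seed = 6)
  f <- fit_logistic(coh, c("age", "sex"), reference_levels = list(sex = "F"))
  rec <- cohort_records(coh)
  beta <- f$coefficients
  lp <- beta[["(Intercept)"]] + beta[["age"]] * rec$age +
    beta[["sexM"]] * (rec$sex == "M")
  manual <- ifelse(stats::plogis(lp) >= 0.5, "Yes", "No")
  expect_equal(as.character(predict_classes(f, coh, 0.5)), manual)
  expect_true(all(predict_classes(f, coh, 0) == "Yes"))
  lo <- predict_classes(f, coh, 1 - 1e-12)
  expect_true(all(lo[stats::plogis(lp) < 0.9] == "No"))
})

test_that("prediction refuses unseen categorical levels by name", {
  coh <- toy_cohort(n = 60, n_events = 15, seed = 8)
  f <- fit_logistic(coh, "sex")
  coh2 <- coh
  levels(coh2$records$sex) <- c("M", "X")
  expect_error(predict_classes(f, coh2), "'X'")
})

test_that("confusion metrics handle the degenerate all-negative classifier", {
  actual <- factor(rep(c("No", "Yes"), c(937, 63)), levels = c("No", "Yes"))
  pred <- factor(rep("No", 1000), levels = c("No", "Yes"))
  m <- confusion_metrics(actual, pred)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_false(m$precision_defined)
  expect_true(is.na(m$precision))
  expect_equal(round(m$accuracy, 2), 0.94)
})

test_that("confusion metrics match hand arithmetic and the perfect case", {
  act <- factor(rep(c("Yes", "No"), c(4, 6)), levels = c("No", "Yes"))
  prd <- factor(c("Yes", "Yes", "Yes", "No", "No", "No", "No", "No", "No", "Yes"),
                levels = c("No", "Yes"))
  m <- confusion_metrics(act, prd)  # tp=3 fn=1 tn=5 fp=1
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 5); expect_equal(m$fn, 1)
  expect_equal(m$sensitivity, 0.75, tolerance = 1e-10)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-10)
  expect_equal(m$precision, 0.75, tolerance = 1e-10)
  expect_equal(m$npv, 5 / 6, tolerance = 1e-10)
  expect_equal(m$accuracy, 0.8, tolerance = 1e-10)

  perfect <- confusion_metrics(act, act)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$accuracy, 1)
  expect_error(confusion_metrics(factor(character(0)), factor(character(0))),
               "empty")
})

test_that("two-proportion test matches the reference implementation", {
  mine <- two_proportion_test(40, 100, 20, 100)
  ref <- stats::prop.test(c(40, 20), c(100, 100), correct = FALSE)
  expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  expect_equal(mine$ci, as.numeric(ref$conf.int), tolerance = 1e-8)

  same <- two_proportion_test(30, 120, 15, 60)
  expect_equal(same$diff, 0)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  zero <- two_proportion_test(0, 50, 0, 80)
  expect_equal(zero$chi2, 0)
  expect_equal(zero$p, 1)

  # Wald symmetry about the difference
  tt <- two_proportion_test(13, 91, 44, 203, conf = 0.9)
  expect_equal(mean(tt$ci), tt$diff, tolerance = 1e-12)
})

test_that("joint Wald test has df = L-1 and collapses to the squared z for binary factors", {
  set.seed(21)
  n <- 600
  sc <- cohort_schema(list(
    schema_variable("race", "categorical", levels = c("A", "B", "C"), role = "predictor"),
    schema_variable("smoking", "categorical", levels = c("No", "Yes"), role = "predictor"),
    schema_variable("y", "categorical", levels = c("No", "Yes"), role = "outcome")))
  df <- data.frame(
    race = sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    smoking = sample(c("No", "Yes"), n, replace = TRUE),
    y = sample(c("No", "Yes"), n, replace = TRUE, prob = c(0.6, 0.4)))
  f <- fit_logistic(cohort(df, sc), c("race", "smoking"))
  w <- wald_factor_test(f, "race")
  expect_equal(w$df, 2L)
  expect_true(w$chi2 >= 0)
  w2 <- wald_factor_test(f, "smoking")
  expect_equal(w2$df, 1L)
  term <- w2$terms[1]
  expect_equal(w2$chi2,
               (f$coefficients[[term]] / f$std_errors[[term]])^2,
               tolerance = 1e-10)
  expect_error(wald_factor_test(f, "age"), "not a categorical predictor")
})

test_that("undersampling shifts the intercept by log of the sampling fraction", {
  cfg <- default_vital_like_config()
  truth <- generating_terms(cfg)
  ok <- 0
  for (s in 1:8) {
    coh <- generate_cohort(cfg, n = 20000, seed = 1000 + s)
    cc <- class_counts(coh)
    res <- select_balanced_undersample(coh, m = 5, seed = s)
    f <- fit_logistic(res$balanced, vital_predictors, reference_levels = vital_refs)
    shift <- log(cc$n_majority / cc$n_minority)  # -log(sampling fraction)
    io <- abs(f$coefficients[["(Intercept)"]] - (cfg$intercept + shift)) <=
      3 * f$std_errors[["(Intercept)"]]
    slopes <- all(abs(f$coefficients[names(truth)] - truth) <=
                    3 * f$std_errors[names(truth)])
    ok <- ok + (io && slopes)
  }
  expect_gte(ok, 7)
})
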