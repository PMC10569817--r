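# shared fixtures (built in code) and independent oracles

# minimal schema: one continuous + two categorical predictors, binary outcome
toy_schema <- function(with_thresholds = FALSE) {
  cohort_schema(
    list(
      schema_variable("age", "continuous", role = "predictor"),
      schema_variable("sex", "categorical", levels = c("M", "F"), role = "predictor"),
      schema_variable("smoking", "categorical", levels = c("No", "Yes"), role = "predictor"),
      schema_variable("cancer", "categorical", levels = c("No", "Yes"), role = "outcome")),
    thresholds = if (with_thresholds)
      list(schema_threshold("age_gt65", "age", 65, c("No", "Yes"))) else list())
}

# random toy cohort with a configurable event count
toy_cohort <- function(n = 200, n_events = 20, seed = 1, with_thresholds = FALSE) {
  set.seed(seed)
  df <- data.frame(
    age = round(runif(n, 50, 90), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    smoking = sample(c("No", "Yes"), n, replace = TRUE, prob = c(0.8, 0.2)),
    cancer = rep("No", n))
  df$cancer[sample(n, n_events)] <- "Yes"
  cohort(df, toy_schema(with_thresholds), provenance = sprintf("toy seed=%d", seed))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# --- independent oracles --------------------------------------------------

# KS statistic by brute force: scan |ECDF difference| at every pooled value
oracle_ks_statistic <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  d <- 0
  for (v in pooled) {
    f1 <- sum(x <= v) / length(x)
    f2 <- sum(y <= v) / length(y)
    d <- max(d, abs(f1 - f2))
  }
  d
}

# Kolmogorov tail from the established C implementation at tight tolerance
oracle_kolmogorov_sf <- function(t) 1 - .Call(stats:::C_pKS2, t, 1e-14)

# Pearson goodness-of-fit from the definition
oracle_chisq_gof <- function(obs, probs) {
  expected <- sum(obs) * probs
  stat <- sum((obs - expected)^2 / expected)
  list(statistic = stat, df = length(obs) - 1,
       p = stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE))
}

# baseline for slope recovery: the generating log-odds under Table-5-style
# baselines, keyed by the glm term names they map to
generating_terms <- function(cfg) {
  co <- cfg$coefficients
  c(age_gt65Yes = unname(co[["age_gt65"]]), sexF = unname(co[["sexF"]]),
    bmi_gt25Yes = unname(co[["bmi_gt25"]]), vitDYes = unname(co[["vitD"]]),
    smokingYes = unname(co[["smoking"]]), raceNHB = unname(co[["raceNHB"]]),
    raceHispanic = unname(co[["raceHispanic"]]))
}

vital_refs <- list(age_gt65 = "No", sex = "M", bmi_gt25 = "No",
                   vitD = "No", smoking = "No", race = "NHW")
vital_predictors <- c("age_gt65", "sex", "bmi_gt25", "vitD", "smoking", "race")
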