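test_that("a candidate equal to the whole population scores p = 1 on categoricals", {
  coh <- toy_cohort(n = 300, n_events = 30, seed = 3)
  rows <- which(cohort_records(coh)$cancer == "No")
  pop <- subset_cohort(coh, rows)
  cs <- score_candidate(pop, pop)
  expect_equal(unname(cs$pvalues[["sex"]]), 1, tolerance = 1e-12)
  expect_equal(unname(cs$pvalues[["smoking"]]), 1, tolerance = 1e-12)
  expect_equal(cs$score, sum(cs$pvalues), tolerance = 1e-12)
  expect_true(all(cs$pvalues >= 0 & cs$pvalues <= 1))
  expect_error(score_candidate(subset_cohort(pop, integer(0)), pop), "empty")
})

test_that("exactly proportional candidate counts give chi-squared 0, p = 1", {
  # population proportions (0.9, 0.1); candidate of 50 with counts (45, 5)
  sc <- cohort_schema(list(
    schema_variable("v", "categorical", levels = c("a", "b"), role = "predictor"),
    schema_variable("y", "categorical", levels = c("No", "Yes"), role = "outcome")))
  pop <- cohort(data.frame(v = rep(c("a", "b"), c(900, 100)), y = "No"), sc)
  cand <- cohort(data.frame(v = rep(c("a", "b"), c(45, 5)), y = "No"), sc)
  cs <- score_candidate(cand, pop, variables = "v")
  expect_equal(unname(cs$pvalues[["v"]]), 1, tolerance = 1e-12)
  g <- chisq_gof(c(45, 5), c(0.9, 0.1))
  expect_equal(g$statistic, 0, tolerance = 1e-12)
})

test_that("KS scoring matches a brute-force ECDF oracle and the reference tail", {
  set.seed(99)
  pop_x <- rnorm(2000, 60, 8)
  cand_x <- sample(pop_x, 200)
  ks <- ks_two_sample(cand_x, pop_x)
  expect_equal(ks$statistic, oracle_ks_statistic(cand_x, pop_x), tolerance = 1e-12)
  expect_equal(ks$p, oracle_kolmogorov_sf(ks$t), tolerance = 1e-8)
})

test_that("chi-squared and KS p-values match reference implementations on random fixtures", {
  set.seed(2024)
  for (i in 1:100) {
    # categorical route
    k <- sample(2:5, 1)
    probs <- as.numeric(rmultinom(1, 500, rep(1, k))) + 1
    probs <- probs / sum(probs)
    obs <- as.numeric(rmultinom(1, sample(50:300, 1), probs))
    if (any(obs + probs == 0)) next
    mine <- chisq_gof(obs, probs)
    orc <- oracle_chisq_gof(obs, probs)
    expect_equal(mine$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(mine$p, orc$p, tolerance = 1e-8)
    # continuous route
    n1 <- sample(20:100, 1); n2 <- sample(100:500, 1)
    x <- rnorm(n1); y <- rnorm(n2, sd = runif(1, 0.5, 2))
    ks <- ks_two_sample(x, y)
    expect_equal(ks$statistic, unname(suppressWarnings(
      stats::ks.test(x, y, exact = FALSE)$statistic)), tolerance = 1e-12)
    expect_equal(ks$p, oracle_kolmogorov_sf(ks$t), tolerance = 1e-8)
    # and the stock asymptotic evaluation agrees to its own truncation scale
    expect_lt(abs(ks$p - suppressWarnings(
      stats::ks.test(x, y, exact = FALSE)$p.value)), 1e-4)
  }
})

test_that("best-of-m selection returns the exhaustive maximum and the degenerate m = 1 draw", {
  coh <- toy_cohort(n = 500, n_events = 40, seed = 5)
  one <- select_balanced_undersample(coh, m = 1, seed = 9, keep_candidates = TRUE)
  expect_equal(one$selected$row_indices, one$candidates[[1]])

  res <- select_balanced_undersample(coh, m = 20, seed = 9, keep_candidates = TRUE)
  pop <- subset_cohort(coh, which(cohort_records(coh)$cancer == "No"))
  rescored <- vapply(res$candidates, function(idx)
    score_candidate(subset_cohort(coh, idx), pop)$score, numeric(1))
  expect_equal(res$candidate_scores, rescored, tolerance = 1e-12)
  expect_equal(res$selected$score, max(rescored), tolerance = 1e-12)
  expect_equal(res$selected$row_indices, res$candidates[[which.max(rescored)]])
})

test_that("the balanced output doubles the minority and uses only real majority rows", {
  coh <- toy_cohort(n = 400, n_events = 35, seed = 8)
  res <- select_balanced_undersample(coh, m = 5, seed = 2)
  rec <- cohort_records(res$balanced)
  expect_equal(nrow(rec), 70L)
  expect_equal(sum(rec$cancer == "Yes"), 35L)
  expect_true(all(res$selected$row_indices %in%
                    which(cohort_records(coh)$cancer == "No")))
  expect_equal(anyDuplicated(res$selected$row_indices), 0L)
})

test_that("identical cohort, m and seed reproduce the result bit-exactly", {
  coh <- toy_cohort(n = 300, n_events = 25, seed = 4)
  a <- select_balanced_undersample(coh, m = 8, seed = 123)
  b <- select_balanced_undersample(coh, m = 8, seed = 123)
  expect_identical(a$selected$row_indices, b$selected$row_indices)
  expect_identical(a$candidate_scores, b$candidate_scores)
  expect_identical(cohort_records(a$balanced), cohort_records(b$balanced))
  c2 <- select_balanced_undersample(coh, m = 8, seed = 124)
  expect_false(identical(a$selected$row_indices, c2$selected$row_indices))
})

test_that("selection scores stochastically dominate with more candidates", {
  coh <- toy_cohort(n = 260, n_events = 30, seed = 6)
  s1 <- vapply(1:50, function(s)
    select_balanced_undersample(coh, m = 1, seed = s)$selected$score, numeric(1))
  s100 <- vapply(1:50, function(s)
    select_balanced_undersample(coh, m = 100, seed = s)$selected$score, numeric(1))
  expect_gt(mean(s100), mean(s1))
})

test_that("stratified undersampling matches minority strata counts exactly", {
  set.seed(31)
  n <- 600
  df <- data.frame(
    age = runif(n, 50, 90),
    sex = sample(c("M", "F"), n, replace = TRUE),
    smoking = sample(c("No", "Yes"), n, replace = TRUE, prob = c(0.85, 0.15)),
    cancer = "No")
  df$cancer[sample(n, 60)] <- "Yes"
  coh <- cohort(df, toy_schema(with_thresholds = TRUE))
  res <- stratified_undersample(coh, strata_vars = c("age_gt65", "sex"),
                                m = 10, seed = 77, keep_candidates = TRUE)
  rec <- cohort_records(coh)
  strat <- interaction(rec[c("age_gt65", "sex")], sep = ":")
  min_tab <- table(strat[rec$cancer == "Yes"])
  sel_tab <- table(strat[res$selected$row_indices])
  expect_equal(as.numeric(sel_tab), as.numeric(min_tab))
  # exact matching: chi-squared statistic of sampled-vs-minority table is 0
  expect_equal(sum((as.numeric(sel_tab) - as.numeric(min_tab))^2 /
                     pmax(as.numeric(min_tab), 1)), 0)
  # stratum variables (and their continuous source) are excluded from scoring
  expect_false(any(c("age", "age_gt65", "sex") %in% names(res$selected$pvalues)))
  # best-of-m oracle under the stratified quotas
  pop <- subset_cohort(coh, which(rec$cancer == "No"))
  rescored <- vapply(res$candidates, function(idx)
    score_candidate(subset_cohort(coh, idx), pop,
                    variables = res$variables)$score, numeric(1))
  expect_equal(res$selected$score, max(rescored), tolerance = 1e-12)
})

test_that("an infeasible minority stratum is reported by name", {
  df <- data.frame(
    age = c(rep(70, 5), rep(55, 10)),
    sex = "M",
    smoking = "No",
    cancer = c(rep("Yes", 4), rep("No", 1), rep("No", 10)))
  coh <- cohort(df, toy_schema(with_thresholds = TRUE))
  expect_error(stratified_undersample(coh, "age_gt65", m = 2, seed = 1),
               "Yes")
})
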