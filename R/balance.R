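#' Score a candidate majority subsample against the majority population
#'
#' Each scored variable contributes one goodness-of-fit p-value measuring how
#' well the candidate reproduces the majority population's distribution:
#' categorical variables via a chi-squared goodness-of-fit test of the
#' candidate's level counts against the population's level proportions,
#' continuous variables via a two-sample Kolmogorov-Smirnov test (asymptotic
#' p-value; the ECDF steps at every observed value, so ties are handled by
#' that convention). The candidate's score is the unweighted sum of the
#' p-values; a score near the number of scored variables means the subsample
#' is distributionally indistinguishable from the population.
#'
#' Population levels with zero members carry zero expected count; they are
#' dropped from the chi-squared table (a candidate drawn from the population
#' cannot contain them). A variable left with fewer than two populated levels
#' cannot discriminate and receives p = 1.
#'
#' @param candidate A [cohort()] slice holding the candidate rows.
#' @param population A [cohort()] slice holding the full majority class.
#' @param variables Variables to score; defaults to every non-derived
#'   predictor in the schema.
#' @return A `candidate_sample`: list with `pvalues` (named), `score`,
#'   `n_rows`, and `row_indices` (populated by the selection functions).
#' @export
score_candidate <- function(candidate, population, variables = NULL) {
  stopifnot(inherits(candidate, "cohort"), inherits(population, "cohort"))
  if (nrow(candidate$records) < 1L) stop("empty candidate")
  variables <- variables %||% schema_predictors(candidate$schema, include_derived = FALSE)
  pv <- score_rows(candidate$records, population$records, variables, candidate$schema)
  structure(list(row_indices = NULL, pvalues = pv, score = sum(pv),
                 n_rows = nrow(candidate$records)),
            class = "candidate_sample")
}

# p-value per variable for a candidate record slice vs the population slice
score_rows <- function(cand, pop, variables, schema) {
  pv <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    info <- schema_get(schema, v)
    if (info$kind == "categorical") {
      pop_tab <- table(pop[[v]])
      keep <- pop_tab > 0L
      if (sum(keep) < 2L) { pv[[v]] <- 1; next }
      obs <- table(cand[[v]])[keep]
      if (sum(obs) < sum(table(cand[[v]])))
        stop("candidate contains level(s) of '", v,
             "' absent from the majority population")
      probs <- as.numeric(pop_tab[keep]) / sum(pop_tab[keep])
      pv[[v]] <- chisq_gof(as.numeric(obs), probs)$p
    } else {
      pv[[v]] <- ks_two_sample(cand[[v]], pop[[v]])$p
    }
  }
  pv
}

majority_minority_rows <- function(x) {
  cc <- class_counts(x)
  out_col <- x$records[[schema_outcome(x$schema)$name]]
  list(majority = which(out_col == cc$majority_level),
       minority = which(out_col == cc$minority_level),
       counts = cc)
}

new_balance_result <- function(balanced, selected, candidate_scores, candidates,
                               method, seed, variables, extra = list()) {
  structure(c(list(balanced = balanced, selected = selected,
                   candidate_scores = candidate_scores,
                   candidates = candidates,
                   n_candidates = length(candidate_scores),
                   method = method, seed = seed, variables = variables),
              extra),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat("balance_result (", x$method, "): ", nrow(x$balanced$records),
      " balanced rows, seed ", x$seed, "\n", sep = "")
  if (!is.null(x$selected)) {
    cat("  best of ", x$n_candidates, " candidates, summed p = ",
        format(x$selected$score, digits = 4), "\n", sep = "")
    print(round(x$selected$pvalues, 4))
  }
  invisible(x)
}

#' Best-of-M distribution-matched undersampling
#'
#' Draws `m` independent simple random samples (without replacement) of size
#' n_minority from the majority class, scores each candidate with
#' [score_candidate()], and keeps the candidate with the highest summed
#' p-value — the subsample most similar, variable by variable, to the whole
#' majority population. The balanced output is that subsample plus every
#' minority row, giving equal class counts. All `m` candidates are drawn up
#' front from a single seeded generator, so candidate c is the c-th draw and
#' results do not depend on scoring order. Score ties are broken in favour of
#' the earliest-drawn candidate.
#'
#' @param x A [cohort()].
#' @param m Number of candidate subsamples (the reference analysis uses
#'   1,000).
#' @param variables Variables to score; defaults to every non-derived
#'   predictor.
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   result.
#' @param keep_candidates Keep each candidate's row indices on the result
#'   (needed to re-score candidates; off by default to save memory).
#' @return A `balance_result`: `balanced` cohort, `selected` candidate (row
#'   indices, per-variable p-values, score), `candidate_scores`, method,
#'   seed.
#' @export
select_balanced_undersample <- function(x, m = 1000L, variables = NULL,
                                        seed = 1L, keep_candidates = FALSE) {
  stopifnot(inherits(x, "cohort"), m >= 1L)
  variables <- variables %||% schema_predictors(x$schema, include_derived = FALSE)
  rows <- majority_minority_rows(x)
  n_min <- rows$counts$n_minority
  if (n_min < 1L) stop("cohort has no minority rows")
  candidates <- with_seed(seed, lapply(seq_len(m), function(i)
    sort(sample(rows$majority, n_min))))
  scored <- lapply(candidates, function(idx)
    score_rows(x$records[idx, , drop = FALSE],
               x$records[rows$majority, , drop = FALSE], variables, x$schema))
  scores <- vapply(scored, sum, numeric(1))
  best <- which.max(scores)  # first maximum = lowest candidate index on ties
  sel_idx <- candidates[[best]]
  balanced <- subset_cohort(x, sort(c(rows$minority, sel_idx)),
                            provenance = paste0(x$provenance,
                                                " [undersampled m=", m,
                                                " seed=", seed, "]"))
  selected <- structure(list(row_indices = sel_idx, pvalues = scored[[best]],
                             score = scores[best], n_rows = n_min),
                        class = "candidate_sample")
  new_balance_result(balanced, selected, scores,
                     if (keep_candidates) candidates else NULL,
                     "plain", seed, variables)
}

#' Stratified best-of-M undersampling
#'
#' Controls chosen confounders (typically an age indicator and sex) by
#' sampling the majority class within strata: the cross of `strata_vars`
#' partitions the cohort, and each candidate draws from every stratum exactly
#' as many majority rows as the minority class has there, so the sampled
#' majority's joint strata distribution equals the minority's exactly.
#' Candidates are drawn jointly (one candidate = one draw in every stratum)
#' and the best of `m` is kept as in [select_balanced_undersample()], but
#' scoring covers only non-stratum variables — the stratum variables (and the
#' continuous sources of threshold-derived stratum indicators) are matched by
#' construction and carry no information.
#'
#' @inheritParams select_balanced_undersample
#' @param strata_vars Categorical (or threshold-derived binary) column names
#'   defining the strata.
#' @return A `balance_result` with method `"stratified"`.
#' @export
stratified_undersample <- function(x, strata_vars, m = 1000L, variables = NULL,
                                   seed = 1L, keep_candidates = FALSE) {
  stopifnot(inherits(x, "cohort"), m >= 1L, length(strata_vars) >= 1L)
  for (sv in strata_vars)
    if (schema_get(x$schema, sv)$kind != "categorical")
      stop("stratum variable '", sv, "' must be categorical ",
           "(use a threshold-derived indicator for continuous measurements)")
  if (is.null(variables)) {
    drop <- strata_vars
    for (th in x$schema$thresholds)
      if (th$name %in% strata_vars) drop <- c(drop, th$source)
    variables <- setdiff(schema_predictors(x$schema, include_derived = FALSE), drop)
  }
  rows <- majority_minority_rows(x)
  strat <- interaction(x$records[strata_vars], drop = FALSE, sep = ":")
  min_tab <- table(strat[rows$minority])
  maj_by_stratum <- split(rows$majority, strat[rows$majority])
  quotas <- min_tab[min_tab > 0L]
  short <- names(quotas)[vapply(names(quotas), function(s)
    length(maj_by_stratum[[s]]) < quotas[[s]], logical(1))]
  if (length(short))
    stop("stratum/strata with fewer majority than minority rows: ",
         paste(short, collapse = ", "))
  candidates <- with_seed(seed, lapply(seq_len(m), function(i)
    sort(unlist(lapply(names(quotas), function(s)
      sample(maj_by_stratum[[s]], quotas[[s]])), use.names = FALSE))))
  scored <- lapply(candidates, function(idx)
    score_rows(x$records[idx, , drop = FALSE],
               x$records[rows$majority, , drop = FALSE], variables, x$schema))
  scores <- vapply(scored, sum, numeric(1))
  best <- which.max(scores)
  sel_idx <- candidates[[best]]
  balanced <- subset_cohort(x, sort(c(rows$minority, sel_idx)),
                            provenance = paste0(x$provenance,
                                                " [stratified undersample m=", m,
                                                " seed=", seed, "]"))
  selected <- structure(list(row_indices = sel_idx, pvalues = scored[[best]],
                             score = scores[best], n_rows = length(sel_idx)),
                        class = "candidate_sample")
  new_balance_result(balanced, selected, scores,
                     if (keep_candidates) candidates else NULL,
                     "stratified", seed, variables,
                     extra = list(strata_vars = strata_vars))
}
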