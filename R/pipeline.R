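#' Run the three-step pipeline end to end
#'
#' Executes undersampling (or SMOTE), logistic regression, and PDP-flatness
#' importance in order: once on the full imbalanced cohort and once on the
#' balanced cohort, so the degenerate-classifier failure mode and its
#' recovery can be read side by side; then per-group fits (the balanced data
#' filtered by the grouping variable) and importance rankings for the pooled
#' model and each group. Every artifact is stamped with the seeds used and an
#' MD5 hash of the canonical configuration, so a rerun with the same config
#' is byte-identical. The input file is never modified.
#'
#' @param config A nested list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{either `list(csv=, schema=)` to load a cohort, or
#'       `list(generator = list(...))` with [generator_config()] overrides
#'       (use `generator = list()` for the defaults).}
#'     \item{balance}{`method` ("plain", "stratified", "smote"), `m`, `seed`,
#'       `strata` (stratified only), `k` (smote only), optional `variables`.}
#'     \item{model}{`predictors`, optional `reference_levels`, `threshold`
#'       (default 0.5), `on_separation` (default "warn": degenerate
#'       separated coefficients are reported as-is with a warning, as
#'       reference analyses of sparse subgroups print them).}
#'     \item{group_by}{optional categorical variable for per-group fits;
#'       `rebalance_within_group = TRUE` re-runs the undersampler inside each
#'       group instead of filtering the pooled balanced data.}
#'     \item{holdout_fraction}{optional; if set, metrics come from a
#'       class-stratified holdout of the balanced data instead of in-sample.}
#'   }
#' @param out_dir Optional directory; when given, writes `balanced.csv`,
#'   `metrics_imbalanced.json`, `metrics_balanced.json`,
#'   `summary_<group>.json`, `importance_<group>.json` and `run_info.json`.
#'   Partial outputs written before a stage failure are preserved.
#' @return The report bundle, invisibly when `out_dir` is given: cohort,
#'   balance result, fits, metric sets, per-group summaries and importance
#'   rankings, seed and config hash.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$model))
  hash <- config_hash(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, obj) {
    if (!is.null(out_dir))
      jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  coh <- stage("input", pipeline_input(config$input))
  bal_cfg <- config$balance %||% list()
  mod_cfg <- config$model
  threshold <- mod_cfg$threshold %||% 0.5
  on_sep <- mod_cfg$on_separation %||% "warn"
  predictors <- unlist(mod_cfg$predictors)
  refs <- as.list(mod_cfg$reference_levels %||% list())

  fit_full <- stage("fit_imbalanced",
    fit_logistic(coh, predictors, reference_levels = refs, on_separation = on_sep))
  met_full <- stage("metrics_imbalanced",
    pipeline_metrics(fit_full, coh, threshold, config$holdout_fraction))
  emit("metrics_imbalanced", c(metrics_json(met_full),
                               list(seed = bal_cfg$seed %||% 1L, config_hash = hash)))

  bal <- stage("balance", pipeline_balance(coh, bal_cfg))
  if (!is.null(out_dir)) write_cohort(bal$balanced, file.path(out_dir, "balanced.csv"))

  fit_bal <- stage("fit_balanced",
    fit_logistic(bal$balanced, predictors, reference_levels = refs,
                 on_separation = on_sep))
  met_bal <- stage("metrics_balanced",
    pipeline_metrics(fit_bal, bal$balanced, threshold, config$holdout_fraction))
  emit("metrics_balanced", c(metrics_json(met_bal),
                             list(seed = bal$seed, config_hash = hash)))

  summaries <- list(All = fit_bal)
  rankings <- list(All = pdp_importance(fit_bal, bal$balanced))
  group_by <- config$group_by
  if (!is.null(group_by)) {
    gv <- if (is.list(group_by)) group_by$variable else group_by
    rebal <- isTRUE(if (is.list(group_by)) group_by$rebalance_within_group else FALSE)
    glev <- schema_get(coh$schema, gv)$levels
    gpred <- setdiff(predictors, gv)
    for (lv in glev) {
      sub <- stage(paste0("group_", lv), {
        if (rebal) {
          rows <- which(coh$records[[gv]] == lv)
          gcoh <- subset_cohort(coh, rows, provenance = paste0(coh$provenance, " [", gv, "=", lv, "]"))
          pipeline_balance(gcoh, bal_cfg)$balanced
        } else {
          rows <- which(bal$balanced$records[[gv]] == lv)
          subset_cohort(bal$balanced, rows,
                        provenance = paste0(bal$balanced$provenance, " [", gv, "=", lv, "]"))
        }
      })
      gfit <- stage(paste0("fit_", lv),
        fit_logistic(sub, gpred, reference_levels = refs, on_separation = on_sep))
      summaries[[lv]] <- gfit
      rankings[[lv]] <- stage(paste0("importance_", lv), pdp_importance(gfit, sub))
    }
  }
  for (nm in names(summaries))
    emit(paste0("summary_", nm), c(fit_json(summaries[[nm]]),
                                   list(config_hash = hash)))
  for (nm in names(rankings))
    emit(paste0("importance_", nm),
         list(scores = as.list(rankings[[nm]]$scores),
              order = rankings[[nm]]$order, config_hash = hash))
  emit("run_info", list(config_hash = hash,
                        balance_method = bal$method,
                        balance_seed = bal$seed,
                        n_input = nrow(coh$records),
                        n_balanced = nrow(bal$balanced$records)))
  res <- list(cohort = coh, balance = bal,
              fit_imbalanced = fit_full, fit_balanced = fit_bal,
              metrics_imbalanced = met_full, metrics_balanced = met_bal,
              summaries = summaries, importance = rankings,
              config_hash = hash)
  if (is.null(out_dir)) res else invisible(res)
}

pipeline_input <- function(input) {
  if (!is.null(input$csv)) {
    load_cohort(input$csv, input$schema,
                missing_policy = input$missing_policy %||% "drop_row")
  } else if (!is.null(input$generator)) {
    cfg <- do.call(generator_config, input$generator)
    generate_cohort(cfg)
  } else stop("config$input needs either csv+schema or a generator block")
}

pipeline_balance <- function(coh, bal_cfg) {
  method <- bal_cfg$method %||% "plain"
  seed <- bal_cfg$seed %||% 1L
  m <- bal_cfg$m %||% 1000L
  vars <- if (!is.null(bal_cfg$variables)) unlist(bal_cfg$variables) else NULL
  switch(method,
    plain = select_balanced_undersample(coh, m = m, variables = vars, seed = seed),
    stratified = stratified_undersample(coh, strata_vars = unlist(bal_cfg$strata),
                                        m = m, variables = vars, seed = seed),
    smote = smote_oversample(coh, k = bal_cfg$k %||% 5L, seed = seed),
    stop("unknown balance method '", method, "'"))
}

# in-sample by default; optional class-stratified holdout split
pipeline_metrics <- function(fit, coh, threshold, holdout_fraction = NULL) {
  out_col <- coh$records[[fit$outcome]]
  if (is.null(holdout_fraction)) {
    pred <- predict_classes(fit, coh, threshold)
    return(confusion_metrics(out_col, pred, event_level = fit$event_level))
  }
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  idx <- with_seed(1L, unlist(lapply(split(seq_along(out_col), out_col),
    function(i) sample(i, max(1L, round(length(i) * holdout_fraction))))))
  train <- subset_cohort(coh, setdiff(seq_along(out_col), idx))
  test <- subset_cohort(coh, idx)
  refit <- fit_logistic(train, fit$predictors,
                        reference_levels = fit$reference_levels,
                        on_separation = "warn")
  pred <- predict_classes(refit, test, threshold)
  confusion_metrics(test$records[[fit$outcome]], pred,
                    event_level = fit$event_level)
}

metrics_json <- function(m) {
  list(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
       sensitivity = m$sensitivity, specificity = m$specificity,
       precision = m$precision, npv = m$npv, accuracy = m$accuracy,
       precision_defined = m$precision_defined, npv_defined = m$npv_defined)
}

fit_json <- function(f) {
  list(coefficients = as.list(f$coefficients),
       std_errors = as.list(f$std_errors),
       aic = f$aic, bic = f$bic, loglik = f$loglik,
       deviance = f$deviance, n_obs = f$n_obs,
       reference_levels = f$reference_levels)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
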