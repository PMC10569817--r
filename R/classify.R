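#' Fit a binary logistic regression to a cohort
#'
#' Maximum-likelihood fit of P(event) = logistic(linear predictor) via
#' iteratively reweighted least squares. Categorical predictors use
#' treatment (reference-level) coding; the reference level defaults to each
#' factor's most frequent level in the data, and can be overridden per
#' factor. The event is the outcome's second declared schema level.
#'
#' Quasi-complete separation inflates a coefficient towards ±infinity with an
#' enormous standard error; by default the fit refuses such degenerate
#' estimates and names the offending term(s) rather than reporting them
#' silently.
#'
#' @param x A [cohort()].
#' @param predictors Character vector of predictor column names.
#' @param reference_levels Named list/character vector, factor name →
#'   reference level, overriding the most-frequent-level default.
#' @param on_separation `"error"` (default) or `"warn"` when a separated term
#'   is detected.
#' @return A `logistic_fit`: coefficients and standard errors (log-odds
#'   scale), covariance matrix, log-likelihood, AIC, BIC, deviance, n_obs,
#'   the reference level used for each factor, and the underlying
#'   [stats::glm()] object.
#' @export
fit_logistic <- function(x, predictors, reference_levels = NULL,
                         on_separation = c("error", "warn")) {
  stopifnot(inherits(x, "cohort"), length(predictors) >= 0L)
  on_separation <- match.arg(on_separation)
  out <- schema_outcome(x$schema)
  dat <- x$records
  refs <- list()
  for (p in predictors) {
    info <- schema_get(x$schema, p)
    col <- dat[[p]]
    if (length(unique(col[!is.na(col)])) < 2L)
      stop("predictor '", p, "' is constant; it cannot enter the model")
    if (info$kind == "categorical") {
      ref <- reference_levels[[p]] %||%
        names(which.max(table(col)))  # most frequent level
      if (!ref %in% info$levels)
        stop("'", ref, "' is not a level of '", p, "'")
      dat[[p]] <- stats::relevel(droplevels(col), ref = ref)
      refs[[p]] <- ref
    }
  }
  # event = second declared outcome level = modelled "success"
  dat[[out$name]] <- factor(dat[[out$name]], levels = out$levels)
  fml <- stats::as.formula(paste(
    out$name, "~",
    if (length(predictors)) paste(predictors, collapse = " + ") else "1"))
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                     control = stats::glm.control(maxit = 100)))
  est <- stats::coef(fit)
  if (anyNA(est))
    stop("aliased (collinear) model terms: ",
         paste(names(est)[is.na(est)], collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  sep <- names(est)[abs(est) > 10 & se > 50]
  if (length(sep)) {
    msg <- paste0("separation detected for term(s): ",
                  paste(sep, collapse = ", "),
                  " (|coefficient| > 10 with SE > 50)")
    if (on_separation == "error") stop(msg) else warning(msg)
  }
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$iter, " IRLS iterations")
  ll <- as.numeric(stats::logLik(fit))
  kterms <- length(est)
  structure(list(
    coefficients = est,
    std_errors = stats::setNames(se, names(est)),
    vcov = stats::vcov(fit),
    loglik = ll,
    aic = -2 * ll + 2 * kterms,
    bic = -2 * ll + log(stats::nobs(fit)) * kterms,
    deviance = fit$deviance,
    n_obs = stats::nobs(fit),
    reference_levels = refs,
    predictors = predictors,
    outcome = out$name,
    event_level = out$levels[2L],
    converged = fit$converged,
    glm = fit), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic_fit: P(", x$outcome, " = ", x$event_level, "), n = ",
      x$n_obs, "\n", sep = "")
  z <- x$coefficients / x$std_errors
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$std_errors, 4),
                    z = round(z, 2),
                    p = signif(2 * stats::pnorm(-abs(z)), 3))
  print(tab)
  cat(sprintf("AIC %.1f  BIC %.1f  logLik %.1f  deviance %.1f\n",
              x$aic, x$bic, x$loglik, x$deviance))
  invisible(x)
}

#' Predict class labels from a logistic fit
#'
#' @param fit A [fit_logistic()] result.
#' @param x A [cohort()] covering every model predictor.
#' @param threshold Probability cut-off; a row is labelled as the event iff
#'   its fitted probability is >= `threshold` (default 0.5).
#' @return Factor of predicted labels over the outcome's two levels.
#' @export
predict_classes <- function(fit, x, threshold = 0.5) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(x, "cohort"),
            threshold >= 0, threshold <= 1)
  dat <- x$records
  for (p in names(fit$glm$xlevels)) {
    seen <- fit$glm$xlevels[[p]]
    new <- setdiff(unique(as.character(dat[[p]])), seen)
    if (length(new))
      stop("level '", new[1L], "' of '", p, "' was not seen when fitting")
    dat[[p]] <- factor(as.character(dat[[p]]), levels = seen)
  }
  prob <- stats::predict(fit$glm, newdata = dat, type = "response")
  lv <- levels(x$records[[fit$outcome]])
  factor(ifelse(prob >= threshold, fit$event_level,
                setdiff(lv, fit$event_level)), levels = lv)
}

#' Clinical performance metrics from a 2x2 confusion table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), precision tp/(tp+fp),
#' negative predictive value tn/(tn+fn), accuracy (tp+tn)/n. Precision and
#' NPV are explicitly flagged as undefined (NA with `precision_defined` /
#' `npv_defined` FALSE) when their denominator is zero — the signature of a
#' degenerate classifier that never predicts one of the classes — rather than
#' silently reported as 0.
#'
#' @param actual,predicted Equal-length factors (or vectors) over the
#'   outcome's two levels.
#' @param event_level The positive/event label; defaults to the second level
#'   of `actual`.
#' @return A `confusion_metrics` object (counts and the five metrics).
#' @export
confusion_metrics <- function(actual, predicted, event_level = NULL) {
  if (length(actual) == 0L) stop("empty label vectors")
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (is.null(event_level)) {
    lv <- if (is.factor(actual)) levels(actual) else sort(unique(as.character(actual)))
    if (length(lv) != 2L) stop("labels must have exactly two levels")
    event_level <- lv[2L]
  }
  act <- as.character(actual) == event_level
  prd <- as.character(predicted) == event_level
  tp <- sum(act & prd); fn <- sum(act & !prd)
  tn <- sum(!act & !prd); fp <- sum(!act & prd)
  div <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    precision = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision_defined = (tp + fp) > 0L,
    npv_defined = (tn + fn) > 0L,
    event_level = event_level), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d (event = '%s')\n",
              x$tp, x$fp, x$tn, x$fn, x$event_level))
  fmt <- function(v, def = TRUE) if (!def) "undefined" else sprintf("%.3f", v)
  cat("  sensitivity ", fmt(x$sensitivity),
      "  specificity ", fmt(x$specificity),
      "  precision ", fmt(x$precision, x$precision_defined),
      "  NPV ", fmt(x$npv, x$npv_defined),
      "  accuracy ", fmt(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Two-proportion comparison
#'
#' Difference of proportions x1/n1 − x2/n2 with a Wald confidence interval
#' (no continuity correction) and the Pearson chi-squared statistic on the
#' underlying 2x2 table (df = 1, no continuity correction). When the pooled
#' proportion is 0 or 1 both groups are degenerate and identical, so the
#' statistic is 0 with p = 1.
#'
#' @param x1,n1 Successes and size of group 1.
#' @param x2,n2 Successes and size of group 2.
#' @param conf Confidence level (default 0.95).
#' @return A `two_prop_test`: `diff`, `ci` (length-2), `chi2`, `df`, `p`,
#'   `p1`, `p2`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, conf = 0.95) {
  stopifnot(n1 >= 1L, n2 >= 1L, x1 >= 0L, x1 <= n1, x2 >= 0L, x2 <= n2,
            conf > 0, conf < 1)
  p1 <- x1 / n1; p2 <- x2 / n2
  diff <- p1 - p2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  halfw <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- diff^2 / (pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(diff = diff, ci = c(diff - halfw, diff + halfw),
                 chi2 = chi2, df = 1L, p = p, p1 = p1, p2 = p2, conf = conf),
            class = "two_prop_test")
}

#' @export
print.two_prop_test <- function(x, ...) {
  cat(sprintf("two-proportion test: diff = %.4f, %g%% CI (%.4f, %.4f)\n",
              x$diff, 100 * x$conf, x$ci[1], x$ci[2]))
  cat(sprintf("  chi-squared = %.3f (df = 1), p = %.4g\n", x$chi2, x$p))
  invisible(x)
}

#' Joint Wald test for a multi-level factor
#'
#' Tests whether all L−1 coefficients of a categorical predictor are jointly
#' zero: W = b' V^{-1} b with b the factor's coefficient block and V the
#' corresponding block of the fitted covariance; W ~ chi-squared with df =
#' L−1 under the null. For a two-level factor this reduces to the squared
#' Wald z-statistic.
#'
#' @param fit A [fit_logistic()] result.
#' @param factor_name Name of a categorical predictor in the fit.
#' @return List with `chi2`, `df`, `p`, and the tested `terms`.
#' @export
wald_factor_test <- function(fit, factor_name) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!factor_name %in% names(fit$glm$xlevels))
    stop("'", factor_name, "' is not a categorical predictor of this fit")
  asn <- attr(stats::model.matrix(fit$glm), "assign")
  labs <- attr(stats::terms(fit$glm), "term.labels")
  idx <- which(asn == match(factor_name, labs))
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  Vinv <- tryCatch(solve(V), error = function(e)
    stop("singular covariance block for factor '", factor_name, "'"))
  chi2 <- drop(t(b) %*% Vinv %*% b)
  df <- length(idx)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       terms = names(b))
}
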