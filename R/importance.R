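#' Partial-dependence curve of a fitted logistic model
#'
#' For each grid value g, every row of the cohort has `variable` overwritten
#' with g, the model's fitted event probabilities are computed, and their
#' mean is recorded — the partial dependence of the predicted response on
#' that variable, with all other columns held at their observed values.
#' Continuous grids use `grid_size` equally spaced quantiles of the observed
#' values (so the grid covers the data's range with equal probability mass
#' between points); categorical grids enumerate the levels seen at fitting.
#' Curves live on the probability (response) scale.
#'
#' @param fit A [fit_logistic()] result.
#' @param x A [cohort()] (typically the data the model was fitted on).
#' @param variable A model predictor.
#' @param grid_size Number of grid points for continuous variables
#'   (default 20; must be >= 2).
#' @return A `pdp_curve`: `variable`, `grid`, `avg_prediction`, `kind`.
#' @export
partial_dependence <- function(fit, x, variable, grid_size = 20L) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(x, "cohort"))
  if (!variable %in% fit$predictors)
    stop("'", variable, "' is not a predictor of this model")
  info <- schema_get(x$schema, variable)
  if (info$kind == "continuous") {
    if (grid_size < 2L) stop("grid_size must be at least 2 for a continuous variable")
    grid <- as.numeric(stats::quantile(x$records[[variable]],
                                       probs = seq(0, 1, length.out = grid_size),
                                       names = FALSE))
  } else {
    grid <- fit$glm$xlevels[[variable]]
  }
  avg <- vapply(grid, function(g) {
    mod <- x
    if (info$kind == "continuous") {
      mod$records[[variable]] <- rep(as.numeric(g), nrow(x$records))
    } else {
      mod$records[[variable]] <- factor(rep(g, nrow(x$records)),
                                        levels = levels(x$records[[variable]]))
    }
    dat <- mod$records
    for (p in names(fit$glm$xlevels))
      dat[[p]] <- factor(as.character(dat[[p]]), levels = fit$glm$xlevels[[p]])
    mean(stats::predict(fit$glm, newdata = dat, type = "response"))
  }, numeric(1))
  structure(list(variable = variable, grid = grid, avg_prediction = avg,
                 kind = info$kind), class = "pdp_curve")
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat("partial dependence of P(event) on '", x$variable, "' (", x$kind, ")\n",
      sep = "")
  print(data.frame(grid = x$grid, avg_prediction = round(x$avg_prediction, 4)))
  invisible(x)
}

#' @export
plot.pdp_curve <- function(x, ...) {
  if (x$kind == "continuous")
    graphics::plot(as.numeric(x$grid), x$avg_prediction, type = "b",
                   xlab = x$variable, ylab = "mean predicted P(event)", ...)
  else
    graphics::barplot(x$avg_prediction, names.arg = x$grid,
                      xlab = x$variable, ylab = "mean predicted P(event)", ...)
  invisible(x)
}

#' PDP-flatness variable importance
#'
#' Ranks predictors by how far their partial-dependence curve departs from a
#' flat line: a flat curve means the model's average prediction ignores the
#' variable. Continuous variables score the sample standard deviation of the
#' curve over its quantile grid; categorical variables score (max − min)/4
#' over the levels — the range/4 convention that puts a two-level factor on
#' the same scale as a normal-ish continuous spread. Variables requested but
#' absent from the model score exactly 0. Ties in the ranking are broken
#' alphabetically.
#'
#' @param fit A [fit_logistic()] result.
#' @param x A [cohort()].
#' @param variables Variables to score; defaults to the model's predictors.
#' @param grid_size Grid size for continuous curves (default 20).
#' @return An `importance_ranking`: named `scores` (input order) and `order`
#'   (variable names, descending score).
#' @export
pdp_importance <- function(fit, x, variables = NULL, grid_size = 20L) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(x, "cohort"))
  variables <- variables %||% fit$predictors
  scores <- stats::setNames(numeric(length(variables)), variables)
  curves <- list()
  for (v in variables) {
    if (!v %in% fit$predictors) { scores[[v]] <- 0; next }
    cv <- partial_dependence(fit, x, v, grid_size = grid_size)
    curves[[v]] <- cv
    scores[[v]] <- if (cv$kind == "continuous") stats::sd(cv$avg_prediction)
                   else (max(cv$avg_prediction) - min(cv$avg_prediction)) / 4
  }
  ord <- names(scores)[order(-scores, names(scores))]
  structure(list(scores = scores, order = ord, curves = curves),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("PDP-flatness importance (descending):\n")
  for (v in x$order)
    cat(sprintf("  %-14s %.5f\n", v, x$scores[[v]]))
  invisible(x)
}

#' @export
plot.importance_ranking <- function(x, ...) {
  s <- rev(x$scores[x$order])
  graphics::barplot(s, horiz = TRUE, las = 1,
                    xlab = "PDP flatness score", ...)
  invisible(x)
}
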