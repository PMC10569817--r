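#' Declare a cohort variable
#'
#' A schema entry describes one column of a cohort table: its name, whether it
#' is categorical or continuous, its admissible levels (categorical only), and
#' its role in the analysis.
#'
#' @param name Column name (unique within a schema).
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels Character vector of admissible level labels, in declared
#'   order. Required for categorical variables, forbidden for continuous ones.
#'   For the outcome variable the *second* declared level is the event level.
#' @param role `"predictor"`, `"outcome"` or `"group"`. Exactly one variable
#'   per schema has role `"outcome"`, and it must be categorical with exactly
#'   two levels (non-event first, event second).
#'
#' @return A `schema_variable` object.
#' @seealso [cohort_schema()]
#' @export
schema_variable <- function(name, kind = c("categorical", "continuous"),
                            levels = NULL, role = c("predictor", "outcome", "group")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 1L)
      stop("categorical variable '", name, "' needs a non-empty `levels` vector")
    levels <- trimws(as.character(levels))
    if (anyDuplicated(levels))
      stop("duplicate levels declared for variable '", name, "'")
  } else if (!is.null(levels)) {
    stop("continuous variable '", name, "' must not declare levels")
  }
  structure(list(name = name, kind = kind, levels = levels, role = role),
            class = "schema_variable")
}

#' Declare a threshold-derived binary indicator
#'
#' Clinical analyses often dichotomize a continuous measurement (age > 65,
#' BMI > 25) while keeping the continuous original available for
#' distributional checks. A threshold rule derives a two-level categorical
#' column from a continuous source column: rows with `source > cutoff` get
#' `labels[2]`, the rest `labels[1]`.
#'
#' @param name Name of the derived column.
#' @param source Name of the continuous source column.
#' @param cutoff Numeric threshold; the indicator is `source > cutoff`.
#' @param labels Length-2 character vector `c(at_or_below, above)`.
#' @return A `schema_threshold` object.
#' @export
schema_threshold <- function(name, source, cutoff, labels = c("No", "Yes")) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(source), length(source) == 1L,
            is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff),
            length(labels) == 2L)
  structure(list(name = name, source = source, cutoff = cutoff,
                 labels = trimws(as.character(labels))),
            class = "schema_threshold")
}

#' Assemble a cohort schema
#'
#' @param variables List of [schema_variable()] entries.
#' @param thresholds Optional list of [schema_threshold()] rules; each derived
#'   column becomes a two-level categorical predictor whose values are
#'   recomputed from its continuous source whenever a cohort is built.
#'
#' @return A `cohort_schema` object.
#' @export
cohort_schema <- function(variables, thresholds = list()) {
  if (inherits(variables, "schema_variable")) variables <- list(variables)
  stopifnot(length(variables) >= 1L,
            all(vapply(variables, inherits, logical(1), "schema_variable")),
            all(vapply(thresholds, inherits, logical(1), "schema_threshold")))
  nms <- vapply(variables, `[[`, character(1), "name")
  tnms <- vapply(thresholds, `[[`, character(1), "name")
  if (anyDuplicated(c(nms, tnms)))
    stop("schema variable names must be unique")
  roles <- vapply(variables, `[[`, character(1), "role")
  out <- which(roles == "outcome")
  if (length(out) != 1L)
    stop("schema must declare exactly one outcome variable, found ", length(out))
  ov <- variables[[out]]
  if (ov$kind != "categorical" || length(ov$levels) != 2L)
    stop("outcome variable '", ov$name,
         "' must be categorical with exactly 2 levels (non-event, event)")
  for (th in thresholds) {
    src <- match(th$source, nms)
    if (is.na(src) || variables[[src]]$kind != "continuous")
      stop("threshold '", th$name, "' needs a continuous source column; '",
           th$source, "' is not one")
  }
  # derived indicators enter the schema as ordinary categorical predictors
  derived <- lapply(thresholds, function(th)
    schema_variable(th$name, "categorical", levels = th$labels, role = "predictor"))
  structure(list(variables = c(variables, derived), thresholds = thresholds),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("cohort schema:", length(x$variables), "variables\n")
  for (v in x$variables) {
    lv <- if (v$kind == "categorical")
      paste0(" {", paste(v$levels, collapse = ", "), "}") else ""
    drv <- if (v$name %in% vapply(x$thresholds, `[[`, character(1), "name"))
      " [derived]" else ""
    cat(sprintf("  %-12s %-11s %-9s%s%s\n", v$name, v$kind, v$role, lv, drv))
  }
  invisible(x)
}

schema_names <- function(schema)
  vapply(schema$variables, `[[`, character(1), "name")

schema_get <- function(schema, name) {
  i <- match(name, schema_names(schema))
  if (is.na(i)) stop("variable '", name, "' is not in the schema")
  schema$variables[[i]]
}

schema_outcome <- function(schema) {
  roles <- vapply(schema$variables, `[[`, character(1), "role")
  schema$variables[[which(roles == "outcome")]]
}

schema_derived_names <- function(schema)
  vapply(schema$thresholds, `[[`, character(1), "name")

#' Names of predictor variables in a schema
#'
#' @param schema A [cohort_schema()].
#' @param include_derived Include threshold-derived indicator columns?
#' @return Character vector of predictor names.
#' @export
schema_predictors <- function(schema, include_derived = TRUE) {
  roles <- vapply(schema$variables, `[[`, character(1), "role")
  nms <- schema_names(schema)[roles == "predictor"]
  if (!include_derived) nms <- setdiff(nms, schema_derived_names(schema))
  nms
}

#' Read or write a schema as YAML
#'
#' The YAML layout has a `variables` list with keys `name`, `kind`, `levels`,
#' `role`, and an optional `thresholds` list with keys `name`, `source`,
#' `cutoff`, `labels`.
#'
#' @param path File path.
#' @return `read_schema()` returns a `cohort_schema`; `write_schema()` its
#'   input, invisibly.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  vars <- lapply(y$variables, function(v)
    schema_variable(v$name, v$kind, levels = unlist(v$levels), role = v$role))
  ths <- lapply(y$thresholds, function(t)
    schema_threshold(t$name, t$source, t$cutoff, unlist(t$labels)))
  cohort_schema(vars, ths)
}

#' @rdname read_schema
#' @param schema A `cohort_schema`.
#' @export
write_schema <- function(schema, path) {
  drv <- schema_derived_names(schema)
  vars <- Filter(function(v) !v$name %in% drv, schema$variables)
  y <- list(
    variables = lapply(vars, function(v) {
      out <- list(name = v$name, kind = v$kind, role = v$role)
      if (!is.null(v$levels)) out$levels <- as.list(v$levels)
      out
    }),
    thresholds = lapply(schema$thresholds, function(t)
      list(name = t$name, source = t$source, cutoff = t$cutoff,
           labels = as.list(t$labels))))
  if (length(y$thresholds) == 0L) y$thresholds <- NULL
  yaml::write_yaml(y, path)
  invisible(schema)
}
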