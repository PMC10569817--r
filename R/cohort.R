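#' Construct a cohort
#'
#' A cohort couples a rectangular record table with its [cohort_schema()] and
#' a free-text provenance tag. Construction validates every categorical cell
#' against the declared levels, recomputes threshold-derived indicator columns
#' from their continuous sources, and rejects rows with a missing outcome.
#'
#' @param records A data frame whose columns cover the schema's non-derived
#'   variable names.
#' @param schema A [cohort_schema()].
#' @param provenance Free-text origin tag (e.g. `"synthetic seed=1"`).
#' @return A `cohort` object (list with `records`, `schema`, `provenance`,
#'   `n_dropped`).
#' @export
cohort <- function(records, schema, provenance = "unspecified") {
  stopifnot(is.data.frame(records), inherits(schema, "cohort_schema"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  drv <- schema_derived_names(schema)
  need <- setdiff(schema_names(schema), drv)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing schema columns: ", paste(miss, collapse = ", "))
  records <- records[, need, drop = FALSE]
  if (nrow(records) < 1L) stop("a cohort needs at least one record")

  for (v in schema$variables) {
    if (v$name %in% drv) next
    col <- records[[v$name]]
    if (v$kind == "categorical") {
      col <- trimws(as.character(col))
      col[!nzchar(col)] <- NA_character_
      bad <- which(!is.na(col) & !col %in% v$levels)
      if (length(bad))
        stop("row ", bad[1L], ", column '", v$name, "': value '",
             col[bad[1L]], "' is not a declared level")
      records[[v$name]] <- factor(col, levels = v$levels)
    } else {
      if (!is.numeric(col)) {
        suppressWarnings(num <- as.numeric(as.character(col)))
        bad <- which(!is.na(col) & is.na(num) & nzchar(trimws(as.character(col))))
        if (length(bad))
          stop("row ", bad[1L], ", column '", v$name, "': value '",
               col[bad[1L]], "' is not numeric")
        col <- num
      }
      records[[v$name]] <- as.numeric(col)
    }
  }
  out <- schema_outcome(schema)
  if (anyNA(records[[out$name]]))
    stop("records with a missing outcome ('", out$name,
         "') cannot enter a cohort; use load_cohort() with missing_policy = 'drop_row'")
  records <- apply_thresholds(records, schema)
  rownames(records) <- NULL
  structure(list(records = records, schema = schema,
                 provenance = provenance, n_dropped = 0L),
            class = "cohort")
}

apply_thresholds <- function(records, schema) {
  for (th in schema$thresholds) {
    src <- records[[th$source]]
    val <- ifelse(src > th$cutoff, th$labels[2L], th$labels[1L])
    records[[th$name]] <- factor(val, levels = th$labels)
  }
  records
}

#' @export
print.cohort <- function(x, ...) {
  cc <- class_counts(x)
  cat("cohort: ", nrow(x$records), " records, ",
      length(x$schema$variables), " variables (", x$provenance, ")\n", sep = "")
  cat("  outcome '", schema_outcome(x$schema)$name, "': ",
      cc$n_minority, " ", cc$minority_level, " (minority) vs ",
      cc$n_majority, " majority\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$records)

#' Cohort record table
#'
#' @param x A [cohort()].
#' @return The underlying data frame (categoricals as factors with the
#'   schema's declared levels).
#' @export
cohort_records <- function(x) {
  stopifnot(inherits(x, "cohort"))
  x$records
}

#' Subset a cohort by row
#'
#' @param x A [cohort()].
#' @param rows Integer row indices (kept in the given order).
#' @param provenance Optional new provenance tag; defaults to the parent's
#'   with a `[subset]` suffix.
#' @return A `cohort` containing the selected rows.
#' @export
subset_cohort <- function(x, rows, provenance = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(provenance)) provenance <- paste(x$provenance, "[subset]")
  rec <- x$records[rows, , drop = FALSE]
  rownames(rec) <- NULL
  out <- x
  out$records <- rec
  out$provenance <- provenance
  if (nrow(rec) < 1L) stop("subset would produce an empty cohort")
  out
}

#' Load a cohort from CSV
#'
#' Reads an RFC-4180 CSV with a header row, validates it against the schema,
#' and applies the missing-data policy. Cell values are trimmed of surrounding
#' whitespace; categorical comparison is case-sensitive. Empty strings count
#' as missing.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema()] (or path to a YAML schema file).
#' @param missing_policy `"drop_row"` deletes any row with a missing value in
#'   a schema column (row-wise deletion, the only supported treatment);
#'   `"error"` refuses to load incomplete data.
#' @param provenance Provenance tag; defaults to the file path.
#' @return A [cohort()]; the number of dropped rows is available as
#'   `$n_dropped` and reported via a message.
#' @export
load_cohort <- function(path, schema, missing_policy = c("drop_row", "error"),
                        provenance = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (is.character(schema)) schema <- read_schema(schema)
  if (is.null(provenance)) provenance <- basename(path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""), colClasses = "character")
  drv <- schema_derived_names(schema)
  need <- setdiff(schema_names(schema), drv)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CSV '", path, "' lacks schema columns: ", paste(miss, collapse = ", "))
  raw <- raw[, need, drop = FALSE]
  for (nm in need) raw[[nm]] <- trimws(raw[[nm]])
  for (nm in need) raw[[nm]][!is.na(raw[[nm]]) & !nzchar(raw[[nm]])] <- NA
  incomplete <- !stats::complete.cases(raw)
  if (any(incomplete) && missing_policy == "error") {
    i <- which(incomplete)[1L]
    j <- names(raw)[which(is.na(raw[i, ]))[1L]]
    stop("missing value at row ", i, ", column '", j,
         "' (missing_policy = 'error')")
  }
  kept <- raw[!incomplete, , drop = FALSE]
  if (nrow(kept) < 1L) stop("no complete rows left after applying drop_row")
  out <- cohort(kept, schema, provenance = provenance)
  out$n_dropped <- sum(incomplete)
  message("load_cohort: kept ", nrow(kept), " rows, dropped ", sum(incomplete))
  out
}

#' Write a cohort to CSV
#'
#' Values round-trip exactly through [load_cohort()]: categoricals are written
#' as their level labels and numerics with full precision.
#'
#' @param x A [cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  for (nm in names(rec)) {
    if (is.factor(rec[[nm]])) rec[[nm]] <- as.character(rec[[nm]])
    else rec[[nm]] <- format(rec[[nm]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(rec, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Relative proportion of a variable's levels within a group
#'
#' For a categorical `variable` and a group defined by `group_var ==
#' group_level`, returns, for each level k of the variable, the fraction of
#' group members taking value k: RP(group, k) = #\{variable = k and group\} /
#' #\{group\}. The proportions sum to one.
#'
#' @param x A [cohort()].
#' @param variable Categorical variable name.
#' @param group_var Categorical grouping variable name (e.g. ethnicity).
#' @param group_level The group level of interest.
#' @return Named numeric vector over the variable's declared levels.
#' @export
relative_proportion <- function(x, variable, group_var, group_level) {
  stopifnot(inherits(x, "cohort"))
  v <- schema_get(x$schema, variable)
  g <- schema_get(x$schema, group_var)
  if (v$kind != "categorical") stop("'", variable, "' is not categorical")
  if (g$kind != "categorical") stop("'", group_var, "' is not categorical")
  if (!group_level %in% g$levels)
    stop("'", group_level, "' is not a declared level of '", group_var, "'")
  in_grp <- x$records[[group_var]] == group_level
  n_grp <- sum(in_grp, na.rm = TRUE)
  if (n_grp == 0L)
    stop("group '", group_var, " = ", group_level,
         "' has no members; relative proportions are undefined")
  counts <- table(x$records[[variable]][in_grp])
  stats::setNames(as.numeric(counts) / n_grp, names(counts))
}

#' Majority/minority class accounting
#'
#' @param x A [cohort()].
#' @return List with `n_majority`, `n_minority`, `minority_level`,
#'   `majority_level`. On an exact tie the level declared *second* in the
#'   schema (the event level) is reported as the minority.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  out <- schema_outcome(x$schema)
  tab <- table(x$records[[out$name]])
  n1 <- as.integer(tab[[out$levels[1L]]])
  n2 <- as.integer(tab[[out$levels[2L]]])
  if (n2 <= n1)  # tie goes to the second-declared (event) level
    list(n_majority = n1, n_minority = n2,
         minority_level = out$levels[2L], majority_level = out$levels[1L])
  else
    list(n_majority = n2, n_minority = n1,
         minority_level = out$levels[1L], majority_level = out$levels[2L])
}
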