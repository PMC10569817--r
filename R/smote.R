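#' SMOTE minority oversampling
#'
#' Generates n_majority − n_minority synthetic minority rows, balancing the
#' classes by oversampling instead of discarding majority rows. Each synthetic
#' row is a uniform convex combination of a randomly chosen minority seed row
#' and one of its k nearest minority neighbours, with distances measured in a
#' standardized numeric feature space: continuous predictors z-scored by the
#' pooled (majority + minority) mean and SD, categorical predictors expanded
#' to 0/1 indicator columns. Threshold-derived indicators are excluded from
#' the feature space (they duplicate their continuous source) and are
#' recomputed from the interpolated source values afterwards.
#'
#' When mapping a synthetic point back to a record, each categorical
#' indicator is rounded to \{0,1\}, which resolves to the level of whichever
#' parent dominates the combination (interpolation weight \eqn{\lambda \le
#' 0.5} keeps the seed row's level). Continuous columns keep their
#' interpolated values.
#'
#' @param x A [cohort()].
#' @param k Number of nearest minority neighbours to draw from (default 5,
#'   the convention of the original technique). Must be < n_minority.
#' @param seed Integer seed.
#' @return A `balance_result` with method `"smote"`; `balanced` holds all
#'   original rows plus the synthetic minority rows (2 × n_majority rows in
#'   total). The `smote` element records, per synthetic row, the parent pair
#'   and interpolation weight, together with the pre-rounding coordinates of
#'   the synthetic point and of both parents in feature space.
#' @export
smote_oversample <- function(x, k = 5L, seed = 1L) {
  stopifnot(inherits(x, "cohort"), k >= 1L)
  rows <- majority_minority_rows(x)
  n_min <- rows$counts$n_minority
  n_syn <- rows$counts$n_majority - n_min
  if (k >= n_min)
    stop("k (", k, ") must be smaller than the minority class size (", n_min, ")")

  enc <- encode_features(x)
  Xmin <- enc$X[rows$minority, , drop = FALSE]
  Z <- scale(enc$X, center = enc$center, scale = enc$scale)
  Zmin <- Z[rows$minority, , drop = FALSE]
  D <- as.matrix(stats::dist(Zmin))
  nn <- do.call(rbind, apply(D, 1L, function(d) order(d)[2L:(k + 1L)],
                             simplify = FALSE))

  draws <- with_seed(seed, list(
    seed_id = sample.int(n_min, n_syn, replace = TRUE),
    nb_pick = sample.int(k, n_syn, replace = TRUE),
    lambda = stats::runif(n_syn)))
  nb_id <- nn[cbind(draws$seed_id, draws$nb_pick)]
  lam <- draws$lambda
  Xa <- Xmin[draws$seed_id, , drop = FALSE]
  Xb <- Xmin[nb_id, , drop = FALSE]
  Xsyn <- (1 - lam) * Xa + lam * Xb

  syn <- decode_synthetic(x, rows$minority[draws$seed_id],
                          rows$minority[nb_id], lam, Xsyn, enc,
                          rows$counts$minority_level)
  combined <- rbind(x$records[, names(syn), drop = FALSE], syn)
  balanced <- cohort(combined, x$schema,
                     provenance = paste0(x$provenance, " [smote k=", k,
                                         " seed=", seed, "]"))
  new_balance_result(
    balanced, selected = NULL, candidate_scores = numeric(0), candidates = NULL,
    method = "smote", seed = seed, variables = enc$feature_vars,
    extra = list(smote = list(
      parents = data.frame(seed_row = rows$minority[draws$seed_id],
                           neighbor_row = rows$minority[nb_id],
                           lambda = lam),
      encoded_synthetic = Xsyn,
      encoded_seed = Xa,
      encoded_neighbor = Xb,
      feature_names = colnames(enc$X),
      k = k)))
}

# numeric encoding of the predictors: continuous as-is, categoricals one-hot
encode_features <- function(x) {
  vars <- schema_predictors(x$schema, include_derived = FALSE)
  cols <- list()
  for (v in vars) {
    info <- schema_get(x$schema, v)
    if (info$kind == "continuous") {
      cols[[v]] <- as.numeric(x$records[[v]])
    } else {
      for (lv in info$levels)
        cols[[paste0(v, "=", lv)]] <- as.numeric(x$records[[v]] == lv)
    }
  }
  X <- do.call(cbind, cols)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(X = X, center = ctr, scale = scl, feature_vars = vars)
}

# map synthetic feature-space points back to schema records
decode_synthetic <- function(x, seed_rows, nb_rows, lam, Xsyn, enc, event_level) {
  n <- length(lam)
  out <- list()
  take_seed <- lam <= 0.5  # indicator rounding keeps the dominant parent
  for (v in setdiff(names(x$records), schema_derived_names(x$schema))) {
    info <- schema_get(x$schema, v)
    if (info$role == "outcome") {
      out[[v]] <- factor(rep(event_level, n), levels = info$levels)
    } else if (info$kind == "continuous" && v %in% colnames(Xsyn)) {
      out[[v]] <- Xsyn[, v]
    } else if (info$kind == "continuous") {
      a <- as.numeric(x$records[[v]][seed_rows])
      b <- as.numeric(x$records[[v]][nb_rows])
      out[[v]] <- (1 - lam) * a + lam * b
    } else {
      a <- as.character(x$records[[v]][seed_rows])
      b <- as.character(x$records[[v]][nb_rows])
      out[[v]] <- factor(ifelse(take_seed, a, b), levels = info$levels)
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  apply_thresholds(df, x$schema)
}
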