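#' Two-sample Kolmogorov-Smirnov test (asymptotic)
#'
#' Statistic D = max |ECDF1 − ECDF2| over the pooled observed values, with
#' the ECDF stepping at every observed value (the usual convention, which is
#' also how ties are handled). The p-value is the asymptotic Kolmogorov tail
#' P(K > t) at t = sqrt(n1 n2 / (n1 + n2)) D, evaluated to machine precision
#' (Jacobi theta form for small t, alternating series otherwise).
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (D), `t`, and `p`.
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(as.numeric(x)); y <- sort(as.numeric(y))
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  z <- sort(c(x, y))
  d <- abs(findInterval(z, x) / n1 - findInterval(z, y) / n2)
  D <- max(d)
  t <- sqrt(n1 * n2 / (n1 + n2)) * D
  list(statistic = D, t = t, p = kolmogorov_sf(t))
}

# P(K > t) for the Kolmogorov distribution; both series are exact, the
# switch at t = 1 picks whichever converges in a handful of terms
kolmogorov_sf <- function(t) {
  if (t < 1e-3) return(1)
  if (t < 1) {
    j <- 1:20
    p <- 1 - sqrt(2 * pi) / t * sum(exp(-(2 * j - 1)^2 * pi^2 / (8 * t^2)))
  } else {
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  }
  min(max(p, 0), 1)
}

#' Chi-squared goodness-of-fit of observed counts against given proportions
#'
#' Thin wrapper over [stats::chisq.test()] (Pearson X^2 with df = k − 1)
#' that suppresses the small-expected-count warning; candidate-vs-population
#' scoring legitimately produces small cells.
#'
#' @param observed Non-negative integer counts.
#' @param probs Expected proportions (same length, summing to 1).
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_gof <- function(observed, probs) {
  stopifnot(length(observed) == length(probs), length(observed) >= 2L)
  ct <- suppressWarnings(stats::chisq.test(as.numeric(observed), p = probs))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
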