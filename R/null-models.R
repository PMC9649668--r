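#' Patefield fixed-marginal null models and metric standardisation
#'
#' The null family used throughout is Patefield's algorithm: random
#' nonnegative integer matrices with exactly the observed row and column
#' totals, drawn from the multiple-hypergeometric (independence)
#' distribution. [stats::r2dtable()] is R's implementation of that
#' algorithm and backs the sampler here.
#'
#' @name null_models
NULL

#' Draw one Patefield null matrix
#'
#' @param row_margins,col_margins nonnegative integer marginal totals; their
#'   sums must agree and be positive.
#' @return an integer matrix with exactly the given margins.
#' @export
patefield_sample <- function(row_margins, col_margins) {
  if (any(row_margins < 0) || any(col_margins < 0))
    stop("margins must be nonnegative", call. = FALSE)
  if (sum(row_margins) != sum(col_margins))
    stop("row and column margins must sum to the same total", call. = FALSE)
  if (sum(row_margins) == 0)
    stop("margins must have positive total", call. = FALSE)
  # a single row (or column) forces the table
  if (length(row_margins) == 1L)
    return(matrix(round(col_margins), nrow = 1L))
  if (length(col_margins) == 1L)
    return(matrix(round(row_margins), ncol = 1L))
  stats::r2dtable(1L, round(row_margins), round(col_margins))[[1L]]
}

#' Summarise an observed metric against a null ensemble
#'
#' Computes the delta transformation (observed minus null mean), the z-score
#' (delta divided by the null standard deviation), the percentile 95%
#' confidence interval of the null values (empirical 2.5 and 97.5 quantiles,
#' linear interpolation), and the significance call: significant when the
#' observed value falls outside the interval.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of the metric on null matrices.
#' @param metric metric name carried into the result.
#' @return a one-row data frame with columns `metric`, `obs`, `null_mean`,
#'   `delta`, `z`, `ci_low`, `ci_high`, `significant`, `n_null`. When the
#'   null ensemble has zero spread but the observed value differs from its
#'   mean, `z` is `NA` and a message is logged.
#' @export
null_summary <- function(observed, null_values, metric = "metric") {
  stopifnot(is.numeric(null_values), length(null_values) >= 2L)
  mu <- mean(null_values)
  sdv <- stats::sd(null_values)
  delta <- observed - mu
  z <- if (sdv > 0) {
    delta / sdv
  } else if (delta == 0) {
    0
  } else {
    message("null ensemble for '", metric,
            "' has zero spread; z undefined")
    NA_real_
  }
  ci <- stats::quantile(null_values, c(0.025, 0.975), names = FALSE)
  data.frame(metric = metric, obs = observed, null_mean = mu, delta = delta,
             z = z, ci_low = ci[1L], ci_high = ci[2L],
             significant = observed < ci[1L] | observed > ci[2L],
             n_null = length(null_values), stringsAsFactors = FALSE)
}

#' Standardise a metric against Patefield nulls
#'
#' Draws `N` Patefield matrices with the margins of `M`, evaluates
#' `metric_fn` on each, and returns the [null_summary()] of the observed
#' value against the ensemble.
#'
#' @param M observed plants x birds frequency matrix (integer counts).
#' @param metric_fn function of one matrix returning a single number; must
#'   be total on all fixed-margin matrices.
#' @param N ensemble size (the analyses in this package use 1000 by
#'   default).
#' @param metric metric name for the output row.
#' @param seed optional integer seed.
#' @return a one-row data frame as in [null_summary()], with the ensemble
#'   attached as attribute `"null_values"`.
#' @export
null_ensemble <- function(M, metric_fn, N = 1000L, metric = "metric",
                          seed = NULL) {
  check_matrix(M)
  if (!is.null(seed)) set.seed(seed)
  draws <- if (nrow(M) == 1L || ncol(M) == 1L) {
    replicate(N, patefield_sample(rowSums(M), colSums(M)),
              simplify = FALSE)  # margins force the table
  } else {
    stats::r2dtable(N, round(rowSums(M)), round(colSums(M)))
  }
  vals <- vapply(draws, function(x) {
    dimnames(x) <- dimnames(M)
    metric_fn(x)
  }, numeric(1))
  out <- null_summary(metric_fn(M), vals, metric = metric)
  attr(out, "null_values") <- vals
  out
}
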