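# Comparison selectivity metrics. These operate on a compound's full profile
# of non-missing percent-inhibition values (targets included), matching how
# they are used as single-number selectivity summaries in the screening
# literature.

check_profile <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    abort_validation("metric profile needs at least 2 measured values")
  }
  if (any(values < 0 | values > 100)) {
    abort_validation("profile values must lie in [0, 100]")
  }
  values
}

#' Gini coefficient of an inhibition profile
#'
#' Inequality of a compound's inhibition across the panel: 0 for a uniformly
#' promiscuous compound, approaching 1 when inhibition is concentrated on few
#' kinases. Population form, no sample correction:
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))`. An all-zero profile returns 0 by
#' convention (an inactive compound has no inequality to measure).
#'
#' The Gini coefficient summarizes the whole footprint without reference to a
#' chosen target, which is precisely why it can conflate "weakly hits
#' everything" with "strongly hits a few" — the contrast the composite
#' selectivity score is built to resolve.
#'
#' @param values Numeric vector of percent-inhibition values (`NA` dropped;
#'   at least 2 measured values required).
#' @return Gini coefficient in \[0, 1\].
#' @examples
#' gini_coefficient(c(80, 0, 0, 0))  # one-hot: (n-1)/n = 0.75
#' @export
gini_coefficient <- function(values) {
  x <- check_profile(values)
  n <- length(x)
  m <- mean(x)
  if (m == 0) return(0)
  xs <- sort(x)
  # sorted identity: sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * m)
}

#' S(x) score of an inhibition profile
#'
#' Fraction of profiled kinases inhibited at or beyond a threshold `x`. A
#' classic hard-threshold selectivity summary: everything below the threshold
#' is invisible to it (a pan-weak compound at 10% scores 0 at any threshold
#' above 10), which motivates threshold-free alternatives.
#'
#' @param values Numeric vector of percent-inhibition values (`NA` dropped).
#' @param x Threshold in percent, in (0, 100].
#' @return Fraction in \[0, 1\].
#' @export
s_score <- function(values, x) {
  vals <- check_profile(values)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 100) {
    abort_validation("S(x) threshold must lie in (0, 100], got %s", format(x))
  }
  mean(vals >= x)
}

#' Append comparison metric columns to a ranked table
#'
#' Adds a `gini` column and one `s_score@x` column per requested threshold,
#' each computed on the compound's full profile of measured values.
#'
#' @param ranked Data frame from [rank_compounds()].
#' @param x An `inhib_matrix` (the matrix `ranked` was computed from).
#' @param s_thresholds Numeric vector of S(x) thresholds in percent.
#' @return `ranked` with extra metric columns; compounds with fewer than two
#'   measured values get `NA`.
#' @export
add_alt_metrics <- function(ranked, x, s_thresholds = c(50)) {
  prof <- lapply(ranked$compound_id, function(id) x$values[id, ])
  safe <- function(f) vapply(prof, function(p) {
    tryCatch(f(p), error = function(e) NA_real_)
  }, numeric(1))
  ranked$gini <- safe(gini_coefficient)
  for (th in s_thresholds) {
    ranked[[sprintf("s_score@%g", th)]] <- safe(function(p) s_score(p, th))
  }
  ranked
}
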