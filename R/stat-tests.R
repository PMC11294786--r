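# Two-group tests used for descriptive comparison and feature screening.

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Computes the U statistic for `group_a` (number of (a, b) pairs with
#' a > b, ties counted half) and the z score
#' `(U - n1*n2/2) / sd` with the tie-corrected variance
#' `n1*n2/12 * ((n + 1) - sum(t^3 - t) / (n*(n-1)))`, where `t` runs over
#' the tied-group sizes; the two-sided p-value comes from the
#' continuity-corrected normal approximation (the half-unit correction
#' keeps the approximation within 0.02 of the exact permutation p down to
#' groups of six). When every observation is tied the variance is zero and
#' `z = 0`, `p = 1`.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @return list with `statistic` (z), `u`, `p_value`, `n`.
#' @examples
#' mann_whitney_z(c(1, 2, 3), c(4, 5, 6))$u # 0
#' @export
mann_whitney_z <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  all_v <- c(group_a, group_b)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    dev <- u - n1 * n2 / 2
    z <- sign(dev) * max(abs(dev) - 0.5, 0) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = z, u = u, p_value = p, n = n)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param table matrix of non-negative counts with positive row and column
#'   sums.
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2))$statistic # 6.667
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Screen features by two-group rank test
#'
#' Retains the features whose two-sided Mann-Whitney p-value comparing
#' cases with controls is below `alpha`; the rest are excluded from the
#' downstream regression (this is how a group-matched quantity such as the
#' LF/HF ratio drops out). No multiplicity correction is applied.
#'
#' @param samples person-time sample table with a `group` column
#'   (`"case"` / `"control"`) and the feature columns.
#' @param features feature columns to screen.
#' @param alpha screening level.
#' @return list with `retained`, `excluded`, and named `p_values`.
#' @export
screen_features <- function(samples, features = nightly_feature_names(),
                            alpha = 0.05) {
  stopifnot("group" %in% names(samples))
  is_case <- samples$group == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop("need at least 2 samples per group")
  }
  p <- vapply(features, function(f) {
    mann_whitney_z(samples[[f]][is_case], samples[[f]][!is_case])$p_value
  }, numeric(1))
  list(retained = features[p < alpha],
       excluded = features[p >= alpha],
       p_values = p)
}
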