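# Diagnostic-accuracy sample-size estimation (precision of Se / Sp).

#' Specification of a sensitivity/specificity precision design
#'
#' @param sensitivity,specificity anticipated proportions, in (0, 1).
#' @param alpha two-sided level of the confidence interval.
#' @param tolerance_fraction relative half-width: the admissible error is
#'   `tolerance_fraction * proportion` (e.g. 0.10 means "within 10% of the
#'   sensitivity").
#' @param case_control_ratio length-2 vector `c(cases, controls)`, e.g.
#'   `c(1, 2)` for a 1:2 design.
#' @param dropout anticipated dropout proportion, in \[0, 1).
#' @return object of class `sample_size_spec`.
#' @export
sample_size_spec <- function(sensitivity = 0.90, specificity = 0.90,
                             alpha = 0.01, tolerance_fraction = 0.10,
                             case_control_ratio = c(1, 2),
                             dropout = 0.10) {
  for (p in c(sensitivity, specificity)) {
    if (p <= 0 || p >= 1) stop("proportions must be in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (tolerance_fraction <= 0) stop("'tolerance_fraction' must be positive")
  if (length(case_control_ratio) != 2 || any(case_control_ratio <= 0)) {
    stop("'case_control_ratio' must be two positive numbers")
  }
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 alpha = alpha, tolerance_fraction = tolerance_fraction,
                 case_control_ratio = case_control_ratio, dropout = dropout),
            class = "sample_size_spec")
}

#' Required group sizes for a diagnostic-accuracy study
#'
#' Normal-approximation precision formula for one proportion:
#' `n = ceil(z^2 * p * (1 - p) / d^2)` with `z` the two-sided
#' `1 - alpha/2` normal quantile and `d = tolerance_fraction * p`.
#' Sensitivity is estimated on cases, specificity on controls; the formula
#' is evaluated for both, the group with the larger demand is sized by it,
#' and the other group follows the design ratio (when the demands tie, the
#' specificity/controls side anchors). Totals are reported both as designed
#' and inflated for dropout (`n / (1 - dropout)`, rounded up).
#'
#' With the defaults (Se = Sp = 0.90, alpha = .01, 10% relative tolerance,
#' 1:2 cases:controls) this gives 37 cases and 74 controls, 111
#' participants in total before dropout inflation.
#'
#' @param spec a [sample_size_spec()].
#' @return list with `n_cases`, `n_controls`, `n_total`, the per-group
#'   precision demands (`demand_cases`, `demand_controls`), `z`, and the
#'   dropout-inflated `n_cases_inflated`, `n_controls_inflated`,
#'   `n_total_inflated`.
#' @examples
#' required_sizes(sample_size_spec())[c("n_cases", "n_controls", "n_total")]
#' @export
required_sizes <- function(spec = sample_size_spec()) {
  stopifnot(inherits(spec, "sample_size_spec"))
  z <- stats::qnorm(1 - spec$alpha / 2)
  n_for <- function(p) {
    d <- spec$tolerance_fraction * p
    ceiling(z^2 * p * (1 - p) / d^2)
  }
  demand_cases <- n_for(spec$sensitivity)
  demand_controls <- n_for(spec$specificity)
  r <- spec$case_control_ratio
  if (demand_controls >= demand_cases) {
    n_controls <- demand_controls
    n_cases <- ceiling(n_controls * r[1] / r[2])
  } else {
    n_cases <- demand_cases
    n_controls <- ceiling(n_cases * r[2] / r[1])
  }
  infl <- function(n) ceiling(n / (1 - spec$dropout))
  list(n_cases = n_cases, n_controls = n_controls,
       n_total = n_cases + n_controls,
       demand_cases = demand_cases, demand_controls = demand_controls,
       z = z,
       n_cases_inflated = infl(n_cases),
       n_controls_inflated = infl(n_controls),
       n_total_inflated = infl(n_cases) + infl(n_controls))
}
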