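# Nightly respiration features from the per-minute respiratory-rate series.

#' Modal nocturnal respiratory rate
#'
#' Rounds each minute's rate to the nearest integer and returns the most
#' frequent value; ties go to the smaller rate.
#'
#' @param rr_per_minute breaths/min, one value per minute, non-empty.
#' @return modal respiratory rate, integer breaths/min.
#' @examples
#' compute_rr_mode(c(15.4, 15.4, 18.0)) # 15
#' @export
compute_rr_mode <- function(rr_per_minute) {
  if (length(rr_per_minute) < 1) stop("empty respiratory-rate series")
  int_mode(rr_per_minute)
}

#' RRF: cumulative tachypnea duration
#'
#' Number of minutes in which the respiratory rate is strictly above
#' 21 breaths/min (a minute at exactly 21 does not count). The minute is
#' the atomic unit, so the result is an integer number of minutes between
#' 0 and the length of the series.
#'
#' @inheritParams compute_rr_mode
#' @return minutes with RR > 21.
#' @examples
#' compute_rrf(c(22, 22, 18, 21)) # 2
#' @export
compute_rrf <- function(rr_per_minute) {
  if (length(rr_per_minute) < 1) stop("empty respiratory-rate series")
  sum(rr_per_minute > 21)
}
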