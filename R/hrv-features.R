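# Nightly HRV / heart-rate features from a beat-interval series.

#' SDNN: sample standard deviation of the beat intervals
#'
#' @param beat_intervals heartbeat intervals (ms), at least 2, all positive.
#' @return SDNN in ms (n-1 denominator, the HRV-standard convention).
#' @examples
#' compute_sdnn(c(790, 810)) # 14.142...
#' @export
compute_sdnn <- function(beat_intervals) {
  if (length(beat_intervals) < 2) stop("need at least 2 beat intervals")
  if (any(beat_intervals <= 0)) stop("beat intervals must be positive")
  stats::sd(beat_intervals)
}

#' Spectral band powers of the nocturnal tachogram
#'
#' Estimates the power of the mean-subtracted beat-interval series in the
#' conventional HRV bands via the Lomb-Scargle periodogram of the
#' irregularly sampled tachogram (interval against beat time), avoiding the
#' interpolation bias of resample-then-FFT estimators. The periodogram is
#' evaluated on a grid with oversampling factor 5 up to 0.5 Hz and rescaled
#' so that its full integral equals the interval variance (Parseval
#' contract); band powers are then the integral over ULF (0, 0.0033) Hz,
#' VLF \[0.0033, 0.04), LF \[0.04, 0.15), HF \[0.15, 0.40), and total power
#' the integral over (0, 0.40\].
#'
#' At least 30 min of data are required; ULF and VLF are only reported for
#' records of 5 h or longer (otherwise `NA`, since slower-than-0.04 Hz
#' rhythms are not meaningfully resolved on part-night records). A
#' constant interval series has zero variance and returns all-zero powers.
#' `lf_hf` is `NA` when the HF power is exactly zero (the ratio is
#' undefined, not infinite).
#'
#' @param beat_times beat times (s), strictly increasing.
#' @param beat_intervals intervals (ms), `length(beat_times) - 1`; interval
#'   `i` ends at `beat_times[i + 1]`.
#' @param ls_method periodogram path, see [ls_periodogram()].
#' @return named list: `tp`, `ulf`, `vlf`, `lf`, `hf` (ms^2) and `lf_hf`.
#' @export
compute_band_powers <- function(beat_times, beat_intervals,
                                ls_method = "fast") {
  if (length(beat_intervals) != length(beat_times) - 1) {
    stop("'beat_intervals' must have length(beat_times) - 1")
  }
  if (any(diff(beat_times) <= 0)) stop("'beat_times' must be strictly increasing")
  span <- max(beat_times) - min(beat_times)
  if (span < 30 * 60) stop("need at least 30 minutes of data for band powers")
  full_night <- span >= 5 * 3600

  t_obs <- beat_times[-1]
  x <- beat_intervals
  if (stats::var(x) < 1e-12) {
    out <- list(tp = 0, ulf = 0, vlf = 0, lf = 0, hf = 0, lf_hf = NA_real_)
    if (!full_night) out$ulf <- out$vlf <- NA_real_
    return(out)
  }

  pg <- ls_periodogram(t_obs, x, fmax = 0.5, ofac = 5, method = ls_method)
  dens <- pg$power * stats::var(x) / (sum(pg$power) * pg$df)
  band_int <- function(lo, hi, right_closed = FALSE) {
    keep <- if (right_closed) pg$freq > lo & pg$freq <= hi
            else pg$freq >= lo & pg$freq < hi
    sum(dens[keep]) * pg$df
  }

  edges <- hrv_bands()
  ulf <- band_int(edges$ulf[1] + 1e-12, edges$ulf[2])
  vlf <- band_int(edges$vlf[1], edges$vlf[2])
  lf <- band_int(edges$lf[1], edges$lf[2])
  hf <- band_int(edges$hf[1], edges$hf[2])
  tp <- band_int(0, 0.40, right_closed = TRUE)
  lf_hf <- if (hf > 0) lf / hf else NA_real_
  if (!full_night) {
    ulf <- NA_real_
    vlf <- NA_real_
  }
  list(tp = tp, ulf = ulf, vlf = vlf, lf = lf, hf = hf, lf_hf = lf_hf)
}

#' Modal nocturnal heart rate
#'
#' Splits the night into elapsed minutes, averages the instantaneous heart
#' rate (60000 / interval) over the beats of each complete minute, rounds
#' each minute to an integer, and returns the most frequent value; ties go
#' to the smaller rate.
#'
#' @inheritParams compute_band_powers
#' @return modal heart rate, integer beats/min.
#' @export
compute_hr_mode <- function(beat_times, beat_intervals) {
  if (length(beat_intervals) != length(beat_times) - 1) {
    stop("'beat_intervals' must have length(beat_times) - 1")
  }
  span <- max(beat_times) - min(beat_times)
  if (span < 60) stop("need at least one full elapsed minute")
  t_obs <- beat_times[-1] - beat_times[1]
  minute <- floor(t_obs / 60)
  complete <- minute < floor(span / 60)
  hr <- 60000 / beat_intervals
  per_min <- tapply(hr[complete], minute[complete], mean)
  int_mode(per_min)
}

#' All nightly features of one recording
#'
#' Combines [compute_sdnn()], [compute_band_powers()], [compute_hr_mode()],
#' [compute_rr_mode()] and [compute_rrf()] into the ten-feature nightly
#' vector used downstream: SDNN, TP, ULF, VLF, LF, HF, LF/HF, modal HR,
#' modal RR, and tachypnea minutes (RRF).
#'
#' @param recording a [night_recording()].
#' @param ls_method periodogram path, see [ls_periodogram()].
#' @return named list of the ten features.
#' @export
compute_nightly_features <- function(recording, ls_method = "fast") {
  stopifnot(inherits(recording, "night_recording"))
  bp <- compute_band_powers(recording$beat_times, recording$beat_intervals,
                            ls_method = ls_method)
  list(
    sdnn = compute_sdnn(recording$beat_intervals),
    tp = bp$tp, ulf = bp$ulf, vlf = bp$vlf, lf = bp$lf, hf = bp$hf,
    lf_hf = bp$lf_hf,
    hr_mode = compute_hr_mode(recording$beat_times, recording$beat_intervals),
    rr_mode = compute_rr_mode(recording$rr_per_minute),
    rrf = compute_rrf(recording$rr_per_minute)
  )
}
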