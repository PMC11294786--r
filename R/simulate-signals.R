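# Per-night signal synthesis: tachogram and per-minute respiration.

# HRV band edges (Hz); left-closed, right-open, ULF open at 0.
hrv_bands <- function() {
  list(ulf = c(0, 0.0033), vlf = c(0.0033, 0.04),
       lf = c(0.04, 0.15), hf = c(0.15, 0.40))
}

#' Simulate a nocturnal beat-interval series with prescribed band powers
#'
#' Synthesizes a tachogram whose spectral content concentrates the requested
#' power (ms^2) in each of the four conventional HRV bands. The interval
#' modulation is built by random-phase spectral synthesis on a uniform time
#' grid: every Fourier line inside a band gets the same amplitude (chosen so
#' the lines sum to the band's target power) and an independent uniform
#' phase. The modulation is added to the mean interval and integrated into
#' beat times: each next beat falls one current interval after the previous
#' one, so `diff(beat_times) * 1000` reproduces `beat_intervals` exactly.
#'
#' A nonzero band must be resolvable at the requested duration: the
#' synthesis grid (frequency step `1/duration`) must place at least 3 lines
#' inside the band, which for the ULF band requires a record longer than
#' ~15 minutes and for VLF longer than ~80 seconds.
#'
#' @param phenotype a [feature_phenotype()]; only `mean_beat_interval` and
#'   `band_powers` are used.
#' @param duration_h record length (hours), `> 0`.
#' @param seed optional integer seed.
#' @return list with `beat_times` (seconds from lights-off, strictly
#'   increasing, first beat at 0) and `beat_intervals` (ms,
#'   `length(beat_times) - 1`).
#' @examples
#' tac <- simulate_tachogram(control_phenotype(), duration_h = 0.5, seed = 1)
#' mean(tac$beat_intervals) # close to the phenotype's 920 ms
#' @export
simulate_tachogram <- function(phenotype, duration_h, seed = NULL) {
  stopifnot(inherits(phenotype, "feature_phenotype"))
  if (duration_h <= 0) stop("'duration_h' must be positive")
  if (!is.null(seed)) set.seed(seed)
  dur <- duration_h * 3600
  mu <- phenotype$mean_beat_interval
  powers <- phenotype$band_powers

  # grid fine enough that linear interpolation at beat times keeps the HF
  # band's power: at 0.125 s the attenuation at 0.4 Hz is about 1%
  dt <- 0.125
  n_grid <- ceiling(dur / dt)
  if (n_grid %% 2 == 1) n_grid <- n_grid + 1
  f_grid <- (1:(n_grid / 2 - 1)) / (n_grid * dt)

  spec <- complex(n_grid)
  for (band in names(powers)) {
    p <- powers[[band]]
    if (p <= 0) next
    edges <- hrv_bands()[[band]]
    idx <- which(f_grid > edges[1] & f_grid < edges[2])
    if (band != "ulf") idx <- which(f_grid >= edges[1] & f_grid < edges[2])
    if (length(idx) < 3) {
      stop(sprintf(
        "record of %.2f h is too short to resolve nonzero %s power (needs >= 3 grid frequencies in band)",
        duration_h, toupper(band)
      ))
    }
    amp <- sqrt(2 * p / length(idx))
    phase <- stats::runif(length(idx), 0, 2 * pi)
    spec[idx + 1] <- spec[idx + 1] + (amp / 2) * exp(1i * phase)
    spec[n_grid + 1 - idx] <- Conj(spec[idx + 1])
  }
  m <- Re(stats::fft(spec, inverse = TRUE))

  # integrate modulated intervals into beat times
  floor_ms <- 0.25 * mu
  beat_times <- numeric(ceiling(dur / (mu / 1000) * 1.6) + 2)
  beat_times[1] <- 0
  k <- 1
  t_cur <- 0
  while (TRUE) {
    pos <- t_cur / dt
    i0 <- floor(pos)
    frac <- pos - i0
    mval <- m[(i0 %% n_grid) + 1] * (1 - frac) + m[((i0 + 1) %% n_grid) + 1] * frac
    iv <- max(mu + mval, floor_ms)
    t_nxt <- t_cur + iv / 1000
    if (t_nxt > dur) break
    k <- k + 1
    beat_times[k] <- t_nxt
    t_cur <- t_nxt
  }
  beat_times <- beat_times[seq_len(k)]
  list(beat_times = beat_times,
       beat_intervals = diff(beat_times) * 1000)
}

#' Simulate a per-minute nocturnal respiratory-rate series
#'
#' One value per elapsed minute. The baseline is the phenotype's mean rate
#' plus smooth (AR(1)-filtered) Gaussian noise with the phenotype's
#' within-night SD, capped at 21 breaths/min so that minutes above the
#' tachypnea threshold come only from injected episodes; the number of
#' episode minutes is Poisson with mean `tachypnea_rate` (truncated at the
#' night's length) and each such minute is set strictly above 21.
#'
#' @param phenotype a [feature_phenotype()]; uses `mean_rr`, `rr_sd` and
#'   `tachypnea_rate`.
#' @param duration_h record length (hours), `> 0`.
#' @param seed optional integer seed.
#' @return numeric vector of breaths/min, one per minute.
#' @examples
#' rr <- simulate_respiration(case_phenotype(), duration_h = 8, seed = 1)
#' sum(rr > 21) # minutes of tachypnea
#' @export
simulate_respiration <- function(phenotype, duration_h, seed = NULL) {
  stopifnot(inherits(phenotype, "feature_phenotype"))
  if (duration_h <= 0) stop("'duration_h' must be positive")
  if (phenotype$tachypnea_rate < 0) stop("negative tachypnea rate")
  if (!is.null(seed)) set.seed(seed)
  n_min <- round(duration_h * 60)
  if (n_min < 1) stop("'duration_h' shorter than one minute")

  base <- rep(phenotype$mean_rr, n_min)
  if (phenotype$rr_sd > 0) {
    eps <- stats::rnorm(n_min)
    sm <- as.numeric(stats::filter(eps, 0.6, method = "recursive"))
    sm <- sm / sqrt(1 / (1 - 0.6^2)) * phenotype$rr_sd
    base <- base + sm
  }
  base <- pmin(pmax(base, 6), 21)

  n_tac <- min(stats::rpois(1, phenotype$tachypnea_rate), n_min)
  if (n_tac > 0) {
    at <- sample.int(n_min, n_tac)
    base[at] <- 21.5 + stats::rexp(n_tac, rate = 1 / 2)
  }
  base
}
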