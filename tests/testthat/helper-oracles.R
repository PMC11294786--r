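# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain brute-force / textbook computations, not as
# calls into the package's own code paths.

# AUC by exhaustive pair counting, ties counted one half.
oracle_auc <- function(scores, labels, positive = "case") {
  s1 <- scores[labels == positive]
  s0 <- scores[labels != positive]
  (sum(outer(s1, s0, ">")) + 0.5 * sum(outer(s1, s0, "=="))) /
    (length(s1) * length(s0))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Textbook Lomb-Scargle power at given frequencies (Scargle's tau-shifted
# least-squares sinusoid fit), in units of x^2.
oracle_ls_power <- function(t, x, freqs) {
  xc <- x - mean(x)
  sapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ph <- w * (t - tau)
    0.5 * (sum(xc * cos(ph))^2 / sum(cos(ph)^2) +
             sum(xc * sin(ph))^2 / sum(sin(ph)^2))
  })
}

# Brute-force night-exclusion rule, one night at a time.
oracle_qc_excluded <- function(motions, sleep_h, loss_min, hr, rr,
                               night_date, windows_start, windows_end) {
  in_exac <- FALSE
  if (length(windows_start)) {
    for (w in seq_along(windows_start)) {
      if (night_date >= windows_start[w] - 7 && night_date <= windows_end[w]) {
        in_exac <- TRUE
      }
    }
  }
  motions >= 600 || sleep_h < 5 || sleep_h > 9 || loss_min >= 60 ||
    hr == 0 || rr == 0 || in_exac
}

# Tiny deterministic tachogram: mean interval plus one sinusoidal interval
# modulation, integrated to beat times.
make_sine_tachogram <- function(freq_hz, amp_ms, mean_ms = 900,
                                duration_s = 8 * 3600) {
  times <- numeric(ceiling(duration_s / (mean_ms / 1000)) + 2)
  k <- 1
  repeat {
    iv <- mean_ms + amp_ms * sin(2 * pi * freq_hz * times[k])
    nxt <- times[k] + iv / 1000
    if (nxt > duration_s) break
    k <- k + 1
    times[k] <- nxt
  }
  times <- times[seq_len(k)]
  list(beat_times = times, beat_intervals = diff(times) * 1000)
}
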