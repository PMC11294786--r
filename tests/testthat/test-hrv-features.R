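# SDNN, Lomb-Scargle band powers, modal heart rate.

test_that("SDNN matches hand and brute-force computations", {
  expect_equal(compute_sdnn(c(800, 800, 800)), 0)
  expect_equal(compute_sdnn(c(790, 810)), sqrt(200), tolerance = 1e-12)
  expect_equal(round(compute_sdnn(c(790, 810)), 3), 14.142)
  set.seed(1)
  x <- runif(1000, 700, 1100)
  two_pass <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(compute_sdnn(x), two_pass, tolerance = 1e-9)
  expect_error(compute_sdnn(900), "at least 2")
  expect_error(compute_sdnn(c(800, -10)), "positive")
})

test_that("fast periodogram agrees with the direct sums and the textbook oracle", {
  set.seed(7)
  t <- sort(runif(400, 0, 2400))
  x <- 35 * sin(2 * pi * 0.07 * t) + rnorm(400, sd = 6)
  pf <- ls_periodogram(t, x, fmax = 0.25, ofac = 4)
  pd <- ls_periodogram(t, x, fmax = 0.25, ofac = 4, method = "direct")
  expect_equal(pf$power, pd$power, tolerance = 1e-3)
  ora <- oracle_ls_power(t, x, pd$freq)
  expect_equal(pd$power, ora, tolerance = 1e-8)
  expect_equal(pd$freq[which.max(pd$power)], 0.07, tolerance = 0.01)
})

test_that("constant intervals give zero total power", {
  tac <- make_sine_tachogram(0.25, 0, duration_s = 3600)
  bp <- compute_band_powers(tac$beat_times, tac$beat_intervals)
  expect_lt(bp$tp, 1e-10)
  expect_true(is.na(bp$lf_hf))
})

test_that("a pure 0.25 Hz interval modulation lands its a^2/2 power in HF", {
  a <- 40
  tac <- make_sine_tachogram(0.25, a, duration_s = 8 * 3600)
  bp <- compute_band_powers(tac$beat_times, tac$beat_intervals)
  expect_equal(bp$hf, a^2 / 2, tolerance = 0.05)
  expect_lt(bp$lf, 0.05 * bp$hf)
  expect_equal(bp$lf_hf, bp$lf / bp$hf)
})

test_that("band powers integrate consistently to the total", {
  tac <- simulate_tachogram(case_phenotype(), duration_h = 6, seed = 11)
  bp <- compute_band_powers(tac$beat_times, tac$beat_intervals)
  s <- bp$ulf + bp$vlf + bp$lf + bp$hf
  expect_lte(abs(bp$tp - s), 0.05 * bp$tp)
  expect_gte(bp$tp, max(bp$ulf, bp$vlf, bp$lf, bp$hf))
})

test_that("scaling interval deviations scales SDNN linearly and powers quadratically", {
  tac <- simulate_tachogram(control_phenotype(), duration_h = 5.5, seed = 2)
  x <- tac$beat_intervals
  xs <- mean(x) + 3 * (x - mean(x))
  expect_equal(compute_sdnn(xs), 3 * compute_sdnn(x), tolerance = 1e-12)
  bp1 <- compute_band_powers(tac$beat_times, x)
  bp2 <- compute_band_powers(tac$beat_times, xs)
  for (b in c("tp", "ulf", "vlf", "lf", "hf")) {
    expect_equal(bp2[[b]], 9 * bp1[[b]], tolerance = 1e-8)
  }
})

test_that("shifting all beat times leaves every feature unchanged", {
  tac <- simulate_tachogram(control_phenotype(), duration_h = 5.5, seed = 4)
  bp1 <- compute_band_powers(tac$beat_times, tac$beat_intervals)
  bp2 <- compute_band_powers(tac$beat_times + 1234.5, tac$beat_intervals)
  expect_equal(bp1, bp2, tolerance = 1e-6)
  expect_equal(compute_hr_mode(tac$beat_times, tac$beat_intervals),
               compute_hr_mode(tac$beat_times + 1234.5, tac$beat_intervals))
})

test_that("part-night records flag the slow bands unavailable", {
  tac <- simulate_tachogram(feature_phenotype(900, ulf = 0, vlf = 0, lf = 500,
                                              hf = 400, mean_rr = 15),
                            duration_h = 1, seed = 9)
  bp <- compute_band_powers(tac$beat_times, tac$beat_intervals)
  expect_true(is.na(bp$ulf) && is.na(bp$vlf))
  expect_gt(bp$hf, 0)
  short <- make_sine_tachogram(0.25, 10, duration_s = 20 * 60)
  expect_error(compute_band_powers(short$beat_times, short$beat_intervals),
               "30 minutes")
})

test_that("modal heart rate follows the per-minute majority with ties to the smaller", {
  tac <- make_sine_tachogram(0.25, 0, mean_ms = 1000, duration_s = 1800)
  expect_equal(compute_hr_mode(tac$beat_times, tac$beat_intervals), 60)
  # 300 minutes at 60 bpm, 150 at 62 bpm -> 60
  iv <- c(rep(1000, 300 * 60), rep(60000 / 62, ceiling(150 * 62)))
  bt <- c(0, cumsum(iv / 1000))
  expect_equal(compute_hr_mode(bt, iv), 60)
  # exact tie between 60 and 62 -> smaller wins
  iv <- c(rep(1000, 10 * 60), rep(60000 / 62, 10 * 62))
  bt <- c(0, cumsum(iv / 1000))
  expect_equal(compute_hr_mode(bt, iv), 60)
  expect_error(compute_hr_mode(c(0, 0.9), 900), "minute")
})
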