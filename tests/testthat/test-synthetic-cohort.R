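# Cohort and per-night signal generation.

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- sim_config(n_cases = 4, n_controls = 4, nights_per_person = 12, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$roster, b$roster)
  expect_identical(a$nights, b$nights)
  expect_identical(a$features, b$features)
  expect_identical(a$windows, b$windows)
})

test_that("full compliance records every scheduled night", {
  cfg <- sim_config(n_cases = 3, n_controls = 3, nights_per_person = 30,
                    compliance = 1.0, seed = 5)
  coh <- generate_cohort(cfg)
  counts <- table(coh$nights$participant_id)
  expect_true(all(counts == 30))
  expect_equal(length(counts), 6)
})

test_that("group sizes must be positive", {
  expect_error(sim_config(n_cases = 0), "positive")
  expect_error(sim_config(n_controls = -3), "positive")
})

test_that("case-control HF contrast is positive and detectable on nightly features", {
  coh <- generate_cohort(sim_config(n_cases = 50, n_controls = 50,
                                    nights_per_person = 30, seed = 99))
  fe <- coh$features
  grp <- coh$roster$group[match(fe$participant_id, coh$roster$participant_id)]
  hf_case <- fe$hf[grp == "case"]
  hf_ctrl <- fe$hf[grp == "control"]
  expect_gt(median(hf_case) - median(hf_ctrl), 0)
  expect_lt(mann_whitney_z(hf_case, hf_ctrl)$p_value, 0.05)
})

test_that("nightly feature table satisfies its structural invariants", {
  coh <- generate_cohort(sim_config(n_cases = 10, n_controls = 10,
                                    nights_per_person = 50, seed = 17))
  fe <- coh$features
  expect_gte(nrow(fe), 500)
  num <- fe[c("sdnn", "tp", "ulf", "vlf", "lf", "hf", "rrf")]
  expect_true(all(num >= 0))
  expect_true(all(fe$tp >= pmax(fe$ulf, fe$vlf, fe$lf, fe$hf)))
  expect_true(all(abs(fe$tp - (fe$ulf + fe$vlf + fe$lf + fe$hf)) <= 0.05 * fe$tp))
  expect_true(all(abs(fe$lf_hf - fe$lf / fe$hf) < 1e-9))
})

test_that("simulated tachograms honour the interval/beat-time contract", {
  for (seed in 1:8) {
    ph <- if (seed %% 2) control_phenotype() else case_phenotype()
    tac <- simulate_tachogram(ph, duration_h = 1, seed = seed)
    expect_true(all(diff(tac$beat_times) > 0))
    expect_true(all(tac$beat_intervals > 0))
    expect_lt(max(abs(diff(tac$beat_times) * 1000 - tac$beat_intervals)), 1e-6)
    expect_lte(max(tac$beat_times) - min(tac$beat_times), 10 * 3600)
  }
})

test_that("zero band powers give a constant tachogram with zero SDNN", {
  ph <- feature_phenotype(mean_beat_interval = 1000, ulf = 0, vlf = 0,
                          lf = 0, hf = 0, mean_rr = 14)
  tac <- simulate_tachogram(ph, duration_h = 1, seed = 1)
  expect_equal(compute_sdnn(tac$beat_intervals), 0)
  expect_equal(mean(tac$beat_intervals), 1000)
  # 1000 ms mean interval is 60 beats/min
  expect_equal(60 / mean(tac$beat_intervals / 1000), 60)
})

test_that("mean beat interval is recovered", {
  tac <- simulate_tachogram(control_phenotype(), duration_h = 2, seed = 3)
  expect_equal(mean(tac$beat_intervals), 920, tolerance = 0.02)
})

test_that("an HF-only tachogram concentrates its power in the HF band", {
  ph <- feature_phenotype(mean_beat_interval = 900, ulf = 0, vlf = 0,
                          lf = 0, hf = 1500, mean_rr = 15)
  tac <- simulate_tachogram(ph, duration_h = 8, seed = 7)
  bp <- compute_band_powers(tac$beat_times, tac$beat_intervals)
  expect_gt(bp$hf, 0.85 * 1500)
  expect_lt(bp$hf, 1.15 * 1500)
  expect_lt(bp$lf, 0.1 * 1500)
})

test_that("unresolvable bands at short durations are refused", {
  expect_error(simulate_tachogram(control_phenotype(), duration_h = 0.2),
               "too short")
  # without ULF/VLF requests a short record is fine
  ph <- feature_phenotype(mean_beat_interval = 900, ulf = 0, vlf = 0,
                          lf = 100, hf = 100, mean_rr = 15)
  expect_silent(simulate_tachogram(ph, duration_h = 0.2, seed = 1))
})

test_that("respiration series has one value per minute and honours degenerate inputs", {
  ph <- feature_phenotype(mean_beat_interval = 900, ulf = 0, vlf = 0, lf = 0,
                          hf = 0, mean_rr = 14, rr_sd = 0, tachypnea_rate = 0)
  rr <- simulate_respiration(ph, duration_h = 1, seed = 1)
  expect_length(rr, 60)
  expect_true(all(rr == 14))
  expect_equal(compute_rrf(rr), 0)
})

test_that("expected tachypnea minutes match the configured rate", {
  ph <- feature_phenotype(mean_beat_interval = 900, ulf = 0, vlf = 0, lf = 0,
                          hf = 0, mean_rr = 15, rr_sd = 1.5,
                          tachypnea_rate = 30)
  rrf <- vapply(1:200, function(s) {
    compute_rrf(simulate_respiration(ph, duration_h = 10, seed = s))
  }, numeric(1))
  expect_gte(mean(rrf), 27)
  expect_lte(mean(rrf), 33)
})

test_that("signal-level cohorts produce valid recordings and extractable features", {
  cfg <- sim_config(n_cases = 2, n_controls = 2, nights_per_person = 3,
                    compliance = 1.0, seed = 21)
  coh <- generate_cohort(cfg, level = "signal")
  expect_null(coh$features)
  expect_length(coh$recordings, 12)
  for (rec in coh$recordings) expect_s3_class(rec, "night_recording")
  coh <- extract_features(coh)
  expect_equal(nrow(coh$features), 12)
  expect_true(all(coh$features$sdnn > 0))
})
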