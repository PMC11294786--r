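# Cohort-level simulation: participants, schedules, nightly latent
# physiology, QC-rule injections, exacerbation windows.

#' Generate a synthetic multi-night monitoring cohort
#'
#' Draws a participant roster (group, demographics, exacerbation windows for
#' cases) and one record per *recorded* night: each scheduled night is kept
#' with probability `config$compliance`. Every recorded night carries QC
#' metadata (artifact-motion count, sleep duration, data-loss minutes) and a
#' latent nightly physiology derived from the group phenotype: a shared
#' between-person lognormal multiplier and independent per-night, per-band
#' lognormal multipliers on the band powers, plus additive person/night
#' shifts on heartbeat interval and respiratory rate.
#'
#' With `level = "features"` (default) the ten nightly features are emitted
#' directly from that latent physiology (total power as the band sum, SDNN
#' as its square root, modal HR/RR from the shifted levels, tachypnea
#' minutes as a truncated Poisson draw). This is the fast path used for
#' cohort-scale analyses. With `level = "signal"` every night additionally
#' gets a full beat-interval series and per-minute respiration via
#' [simulate_tachogram()] and [simulate_respiration()], from the same
#' latent nightly targets; features are then obtained with
#' [extract_features()]. Signal synthesis costs a few hundred ms per night,
#' so use it for small cohorts.
#'
#' A configurable fraction of recorded nights is overridden to violate one
#' QC rule (metadata-only, independent of the signal): motion count in
#' 600-900, sleep shorter than 5 h or longer than 9 h, data loss of
#' 60-240 min, or a zeroed vital (modal HR or RR set to 0; in signal mode a
#' zeroed respiration channel).
#'
#' @param config a [sim_config()].
#' @param level `"features"` or `"signal"`.
#' @return object of class `night_cohort`: list with `roster`, `windows`
#'   (exacerbation intervals), `nights` (QC metadata), `features` (nightly
#'   feature table; `NULL` until [extract_features()] for `"signal"`),
#'   `recordings` (named list of `night_recording`s, `"signal"` only) and
#'   the `config`.
#' @examples
#' coh <- generate_cohort(sim_config(n_cases = 3, n_controls = 3,
#'                                   nights_per_person = 10, seed = 7))
#' head(coh$features)
#' @export
generate_cohort <- function(config, level = c("features", "signal")) {
  stopifnot(inherits(config, "sim_config"))
  level <- match.arg(level)
  set.seed(config$seed)

  n_tot <- config$n_cases + config$n_controls
  ids <- sprintf("P%03d", seq_len(n_tot))
  groups <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

  roster <- data.frame(
    participant_id = ids,
    group = groups,
    age = ifelse(groups == "case",
                 pmin(pmax(round(stats::rnorm(n_tot, 73, 7)), 45), 92),
                 pmin(pmax(round(stats::rnorm(n_tot, 57, 8)), 45), 88)),
    sex = ifelse(stats::runif(n_tot) < ifelse(groups == "case", 0.81, 0.37),
                 "male", "female"),
    bmi_category = ifelse(
      groups == "case",
      sample(c("<18.5", "18.5-24", ">=24"), n_tot, TRUE, c(0.16, 0.76, 0.08)),
      sample(c("<18.5", "18.5-24", ">=24"), n_tot, TRUE, c(0.02, 0.61, 0.37))
    ),
    stringsAsFactors = FALSE
  )

  npp <- config$nights_per_person
  n_sched <- if (length(npp) == 1) {
    rep(as.integer(round(npp)), n_tot)
  } else {
    pmax(5L, as.integer(round(stats::rlnorm(n_tot, log(npp[1]), npp[2]))))
  }
  start <- config$start_date + sample.int(365, n_tot, replace = TRUE) - 1L

  windows <- list()
  nights <- list()
  features <- list()
  recordings <- list()

  for (i in seq_len(n_tot)) {
    ph <- if (groups[i] == "case") config$case else config$control
    sched <- start[i] + 0:(n_sched[i] - 1)

    # exacerbation episodes (cases only)
    if (groups[i] == "case" && config$exacerbation_rate > 0) {
      n_ev <- stats::rpois(1, config$exacerbation_rate * n_sched[i] / 30)
      if (n_ev > 0) {
        w_start <- start[i] + sample.int(n_sched[i], n_ev, replace = TRUE) - 1L
        w_len <- sample(3:10, n_ev, replace = TRUE)
        windows[[length(windows) + 1]] <- data.frame(
          participant_id = ids[i],
          exacerbation_start = w_start,
          exacerbation_end = w_start + w_len - 1L
        )
      }
    }

    rec <- stats::runif(n_sched[i]) < config$compliance
    nr <- sum(rec)
    if (nr == 0) next
    dates <- sched[rec]

    # person-level latent physiology: one shared amplitude multiplier plus
    # one extra multiplier per band pair (ULF,VLF) / (LF,HF). Overall HRV
    # level and the slow-vs-fast band balance vary between persons, while
    # within-pair ratios (in particular LF/HF) stay person-invariant.
    ps <- ph$person_sd
    pb <- ph$person_band_sd
    b_person <- stats::rlnorm(1, -ps^2 / 2, ps) *
      stats::rlnorm(2, -pb^2 / 2, pb)[c(1, 1, 2, 2)]
    hr_person <- stats::rnorm(1, 0, ph$hr_person_sd)
    rr_person <- stats::rnorm(1, 0, ph$rr_person_sd)
    ts <- ph$tachypnea_person_sd
    tac_person <- ph$tachypnea_rate * stats::rlnorm(1, -ts^2 / 2, ts)

    # night-level latent physiology
    ns <- ph$night_to_night_sd
    mult <- matrix(stats::rlnorm(4 * nr, -ns^2 / 2, ns), nrow = nr)
    colnames(mult) <- names(ph$band_powers)
    bands <- sweep(mult, 2, ph$band_powers * b_person, `*`)
    mu_night <- ph$mean_beat_interval + hr_person +
      stats::rnorm(nr, 0, ph$hr_night_sd)
    mu_night <- pmax(mu_night, 400)
    rr_night <- pmax(ph$mean_rr + rr_person + stats::rnorm(nr, 0, ph$rr_night_sd), 8)
    sleep_h <- pmin(pmax(stats::rnorm(nr, 7, 0.6), 5.2), 8.8)
    motions <- stats::rpois(nr, 60)
    loss_min <- pmin(round(stats::rexp(nr, 1 / 8)), 45)
    rrf <- pmin(stats::rpois(nr, tac_person), round(sleep_h * 60))

    # QC-rule injections (metadata overrides, one rule per draw)
    qv <- config$qc_violation_rates
    inj_motion <- stats::runif(nr) < qv["motion"]
    inj_short <- stats::runif(nr) < qv["sleep_short"]
    inj_long <- stats::runif(nr) < qv["sleep_long"] & !inj_short
    inj_loss <- stats::runif(nr) < qv["data_loss"]
    inj_zero <- stats::runif(nr) < qv["zero_vital"]
    zero_is_hr <- stats::runif(nr) < 0.5
    motions[inj_motion] <- 600L + sample.int(300, sum(inj_motion), replace = TRUE) - 1L
    sleep_h[inj_short] <- stats::runif(sum(inj_short), 3.5, 4.99)
    sleep_h[inj_long] <- stats::runif(sum(inj_long), 9.01, 10)
    loss_min[inj_loss] <- round(stats::runif(sum(inj_loss), 60, 240))

    hr_mode <- as.integer(round(60000 / mu_night))
    rr_mode <- as.integer(round(rr_night))
    hr_mode[inj_zero & zero_is_hr] <- 0L
    rr_mode[inj_zero & !zero_is_hr] <- 0L
    rrf[inj_zero & !zero_is_hr] <- 0L

    nights[[length(nights) + 1]] <- data.frame(
      participant_id = ids[i], night_date = dates,
      artifact_motions = motions, sleep_duration = sleep_h,
      data_loss_minutes = loss_min, stringsAsFactors = FALSE
    )

    if (level == "features") {
      # small estimator noise on the total-power integral: measured TP is
      # never the exact band sum, and features stay linearly independent
      tp <- rowSums(bands) * exp(stats::rnorm(nr, 0, 0.008))
      features[[length(features) + 1]] <- data.frame(
        participant_id = ids[i], night_date = dates,
        sdnn = sqrt(tp), tp = tp,
        ulf = bands[, "ulf"], vlf = bands[, "vlf"],
        lf = bands[, "lf"], hf = bands[, "hf"],
        lf_hf = bands[, "lf"] / bands[, "hf"],
        hr_mode = hr_mode, rr_mode = rr_mode, rrf = as.numeric(rrf),
        stringsAsFactors = FALSE
      )
    } else {
      for (j in seq_len(nr)) {
        ph_night <- ph
        ph_night$mean_beat_interval <- mu_night[j]
        ph_night$band_powers <- bands[j, ]
        ph_night$mean_rr <- rr_night[j]
        ph_night$tachypnea_rate <- tac_person
        tac <- simulate_tachogram(ph_night, duration_h = sleep_h[j])
        rr <- simulate_respiration(ph_night, duration_h = sleep_h[j])
        # a zeroed-vital night is a dead respiration channel in signal mode
        if (inj_zero[j]) rr[] <- 0
        key <- paste0(ids[i], "_", format(dates[j]))
        recordings[[key]] <- night_recording(
          participant_id = ids[i], night_date = dates[j],
          beat_times = tac$beat_times, beat_intervals = tac$beat_intervals,
          rr_per_minute = rr,
          artifact_motions = motions[j], sleep_duration = sleep_h[j],
          data_loss_minutes = loss_min[j]
        )
      }
    }
  }

  structure(
    list(
      roster = roster,
      windows = if (length(windows)) do.call(rbind, windows) else
        data.frame(participant_id = character(),
                   exacerbation_start = as.Date(character()),
                   exacerbation_end = as.Date(character())),
      nights = do.call(rbind, nights),
      features = if (level == "features") do.call(rbind, features) else NULL,
      recordings = if (level == "signal") recordings else NULL,
      config = config
    ),
    class = "night_cohort"
  )
}

#' One night of recorded vital signs
#'
#' Container for a single night: the beat-time / beat-interval series, the
#' per-minute respiratory-rate series, and QC metadata. Validates the core
#' invariants: beat times strictly increasing, intervals positive and equal
#' to successive beat-time differences (ms) within 1e-6, recording span at
#' most 10 h.
#'
#' @param participant_id,night_date identifiers.
#' @param beat_times seconds from lights-off, strictly increasing.
#' @param beat_intervals ms, `length(beat_times) - 1`.
#' @param rr_per_minute breaths/min, one per elapsed minute.
#' @param artifact_motions,sleep_duration,data_loss_minutes QC metadata.
#' @return object of class `night_recording`.
#' @export
night_recording <- function(participant_id, night_date, beat_times,
                            beat_intervals, rr_per_minute,
                            artifact_motions, sleep_duration,
                            data_loss_minutes) {
  if (length(beat_intervals) != length(beat_times) - 1) {
    stop("'beat_intervals' must have length(beat_times) - 1")
  }
  if (any(diff(beat_times) <= 0)) stop("'beat_times' must be strictly increasing")
  if (any(beat_intervals <= 0)) stop("beat intervals must be positive")
  if (max(abs(diff(beat_times) * 1000 - beat_intervals)) > 1e-6) {
    stop("'beat_intervals' inconsistent with diff(beat_times)")
  }
  if (max(beat_times) - min(beat_times) > 10 * 3600) {
    stop("recording span exceeds 10 h")
  }
  structure(
    list(participant_id = participant_id, night_date = as.Date(night_date),
         beat_times = beat_times, beat_intervals = beat_intervals,
         rr_per_minute = rr_per_minute,
         artifact_motions = artifact_motions,
         sleep_duration = sleep_duration,
         data_loss_minutes = data_loss_minutes),
    class = "night_recording"
  )
}

#' Extract the nightly feature table from recorded signals
#'
#' Runs [compute_nightly_features()] over every recording of a
#' `level = "signal"` cohort and returns (and attaches) the nightly feature
#' table in the same layout that `level = "features"` emits directly.
#'
#' @param cohort a `night_cohort` with recordings.
#' @param ls_method periodogram evaluation path, see [ls_periodogram()].
#' @return the cohort with `$features` filled in.
#' @export
extract_features <- function(cohort, ls_method = "fast") {
  stopifnot(inherits(cohort, "night_cohort"))
  if (is.null(cohort$recordings)) {
    stop("cohort has no recordings; generate with level = \"signal\"")
  }
  rows <- lapply(cohort$recordings, function(rec) {
    fe <- compute_nightly_features(rec, ls_method = ls_method)
    data.frame(participant_id = rec$participant_id,
               night_date = rec$night_date,
               as.data.frame(fe), stringsAsFactors = FALSE)
  })
  cohort$features <- do.call(rbind, rows)
  rownames(cohort$features) <- NULL
  cohort
}
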