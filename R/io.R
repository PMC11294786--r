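# Delimited-text serialization of cohorts (UTF-8, '.' decimal, header row).

#' Write a cohort to a directory of CSV files
#'
#' Layout: `roster.csv` (participant_id, group, age, sex, bmi_category,
#' exacerbation_start, exacerbation_end — one row per exacerbation window,
#' window columns empty for participants without any), `nights_index.csv`
#' (QC metadata per recorded night), `nightly_features.csv` (when features
#' are present), and for signal-level cohorts one `night_<id>_<date>.csv`
#' per recording with a `block` column separating the beat block
#' (beat_time_s, value = interval_ms, first beat's interval empty) from the
#' per-minute respiration block (minute_index, value = breaths/min).
#'
#' @param cohort a `night_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "night_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- cohort$windows
  roster <- merge(cohort$roster, w, by = "participant_id", all.x = TRUE)
  utils::write.csv(roster, file.path(dir, "roster.csv"), row.names = FALSE)
  utils::write.csv(cohort$nights, file.path(dir, "nights_index.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$features)) {
    utils::write.csv(cohort$features, file.path(dir, "nightly_features.csv"),
                     row.names = FALSE)
  }
  for (rec in cohort$recordings %||% list()) {
    beats <- data.frame(block = "beat",
                        index = rec$beat_times,
                        value = c(NA, rec$beat_intervals))
    rr <- data.frame(block = "rr",
                     index = seq_along(rec$rr_per_minute) - 1,
                     value = rec$rr_per_minute)
    utils::write.csv(rbind(beats, rr),
                     file.path(dir, sprintf("night_%s_%s.csv",
                                            rec$participant_id,
                                            format(rec$night_date))),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the CSV layout.
#' @return a `night_cohort` (without a config).
#' @export
read_cohort <- function(dir) {
  roster_full <- utils::read.csv(file.path(dir, "roster.csv"),
                                 stringsAsFactors = FALSE)
  windows <- roster_full[!is.na(roster_full$exacerbation_start),
                         c("participant_id", "exacerbation_start",
                           "exacerbation_end")]
  windows$exacerbation_start <- as.Date(windows$exacerbation_start)
  windows$exacerbation_end <- as.Date(windows$exacerbation_end)
  roster <- unique(roster_full[, c("participant_id", "group", "age", "sex",
                                   "bmi_category")])
  rownames(roster) <- NULL
  nights <- utils::read.csv(file.path(dir, "nights_index.csv"),
                            stringsAsFactors = FALSE)
  nights$night_date <- as.Date(nights$night_date)

  features <- NULL
  fpath <- file.path(dir, "nightly_features.csv")
  if (file.exists(fpath)) {
    features <- utils::read.csv(fpath, stringsAsFactors = FALSE)
    features$night_date <- as.Date(features$night_date)
  }

  rec_files <- list.files(dir, pattern = "^night_.*\\.csv$", full.names = TRUE)
  recordings <- NULL
  if (length(rec_files)) {
    recordings <- list()
    for (f in rec_files) {
      parts <- sub("^night_", "", sub("\\.csv$", "", basename(f)))
      pid <- sub("_.*$", "", parts)
      date <- as.Date(sub("^[^_]*_", "", parts))
      d <- utils::read.csv(f, stringsAsFactors = FALSE)
      beats <- d[d$block == "beat", ]
      rr <- d[d$block == "rr", ]
      meta <- nights[nights$participant_id == pid & nights$night_date == date, ]
      recordings[[paste0(pid, "_", format(date))]] <- night_recording(
        participant_id = pid, night_date = date,
        beat_times = beats$index,
        beat_intervals = beats$value[-1],
        rr_per_minute = rr$value,
        artifact_motions = meta$artifact_motions[1],
        sleep_duration = meta$sleep_duration[1],
        data_loss_minutes = meta$data_loss_minutes[1]
      )
    }
  }

  structure(list(roster = roster, windows = windows, nights = nights,
                 features = features, recordings = recordings, config = NULL),
            class = "night_cohort")
}
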