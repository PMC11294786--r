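# Night-level quality-control exclusions applied before any aggregation.

#' Apply the five night-level exclusion rules
#'
#' A recorded night is excluded when any of the following holds:
#' \itemize{
#'   \item `motion`: 600 or more artifact motions (boundary inclusive);
#'   \item `sleep_short` / `sleep_long`: sleep strictly shorter than 5 h or
#'     strictly longer than 9 h (exactly 5 h or 9 h is kept);
#'   \item `data_loss`: 60 or more minutes of data loss (boundary
#'     inclusive);
#'   \item `zero_vital`: a modal heart rate or respiratory rate of 0;
#'   \item `exacerbation`: the night date falls within 7 calendar days
#'     before the start of, or anywhere during, an acute-exacerbation
#'     window of that participant (`[start - 7, end]`).
#' }
#' Decisions are per-night and order-free; a night is kept iff its reason
#' set is empty.
#'
#' @param nights data frame with `participant_id`, `night_date`,
#'   `artifact_motions`, `sleep_duration` (hours), `data_loss_minutes`.
#' @param features nightly feature table with `participant_id`,
#'   `night_date`, `hr_mode`, `rr_mode` (same nights).
#' @param roster participant roster; all nights must reference known
#'   participants.
#' @param windows exacerbation windows: `participant_id`,
#'   `exacerbation_start`, `exacerbation_end` (one row per window), or
#'   `NULL` for none.
#' @return data frame of QC decisions: `participant_id`, `night_date`,
#'   `kept` (logical), `reasons` (comma-joined subset of the rule tags,
#'   empty string when kept).
#' @export
apply_night_exclusions <- function(nights, features, roster, windows = NULL) {
  unknown <- setdiff(unique(nights$participant_id), roster$participant_id)
  if (length(unknown)) {
    stop("nights reference unknown participant(s): ",
         paste(unknown, collapse = ", "))
  }
  key <- function(d) paste(d$participant_id, format(d$night_date))
  fi <- match(key(nights), key(features))
  if (anyNA(fi)) stop("every night needs a matching feature row")
  hr <- features$hr_mode[fi]
  rr <- features$rr_mode[fi]

  n <- nrow(nights)
  reason <- matrix(FALSE, n, 6,
                   dimnames = list(NULL, c("motion", "sleep_short", "sleep_long",
                                           "data_loss", "zero_vital",
                                           "exacerbation")))
  reason[, "motion"] <- nights$artifact_motions >= 600
  reason[, "sleep_short"] <- nights$sleep_duration < 5
  reason[, "sleep_long"] <- nights$sleep_duration > 9
  reason[, "data_loss"] <- nights$data_loss_minutes >= 60
  reason[, "zero_vital"] <- hr == 0 | rr == 0

  if (!is.null(windows) && nrow(windows)) {
    for (w in seq_len(nrow(windows))) {
      hit <- nights$participant_id == windows$participant_id[w] &
        nights$night_date >= windows$exacerbation_start[w] - 7 &
        nights$night_date <= windows$exacerbation_end[w]
      reason[hit, "exacerbation"] <- TRUE
    }
  }

  reasons <- apply(reason, 1, function(r) paste(colnames(reason)[r], collapse = ","))
  data.frame(
    participant_id = nights$participant_id,
    night_date = nights$night_date,
    kept = !apply(reason, 1, any),
    reasons = reasons,
    stringsAsFactors = FALSE
  )
}

#' Keep only QC-passing nights of a feature table
#'
#' @param features nightly feature table.
#' @param decisions output of [apply_night_exclusions()].
#' @return the kept rows of `features`.
#' @export
filter_kept_nights <- function(features, decisions) {
  key <- function(d) paste(d$participant_id, format(d$night_date))
  keep_keys <- key(decisions)[decisions$kept]
  features[key(features) %in% keep_keys, , drop = FALSE]
}
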