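# Multi-day trimmed-mean aggregation into person-time samples.

#' Trimmed t-day mean
#'
#' For a window of `t >= 3` nightly values: subtract one occurrence of the
#' maximum and one of the minimum from the sum and divide by `t - 2`. For
#' `t = 1` the nightly value itself is returned (the trimming formula is
#' undefined there and the single night is the sample). `t = 2` is an
#' error: after removing the maximum and minimum nothing remains.
#'
#' @param values exactly the window's `t` finite nightly values.
#' @return the trimmed mean.
#' @examples
#' trimmed_mean(1:7) # (28 - 7 - 1) / 5 = 4
#' @export
trimmed_mean <- function(values) {
  t_len <- length(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (t_len == 1) return(values)
  if (t_len == 2) stop("trimmed mean is undefined for a 2-night window")
  (sum(values) - max(values) - min(values)) / (t_len - 2)
}

#' Build person-time samples of t-day trimmed-mean features
#'
#' One sample per (participant, anchor night) for which the anchor night
#' and its `t - 1` most recent earlier kept nights exist; the window is
#' those `t` kept nights (rolling, calendar gaps allowed). Participants
#' with fewer than `t` kept nights contribute no samples. For `t = 1`
#' every kept night is its own sample.
#'
#' @param features QC-filtered nightly feature table (`participant_id`,
#'   `night_date`, feature columns).
#' @param t window length in nights (1 or >= 3).
#' @param feature_cols feature columns to aggregate.
#' @return data frame: `participant_id`, `anchor_night_date`, `t`, one
#'   trimmed-mean column per feature.
#' @export
build_samples <- function(features, t,
                          feature_cols = nightly_feature_names()) {
  if (!(t == 1 || t >= 3)) stop("'t' must be 1 or >= 3")
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  ord <- order(features$participant_id, features$night_date)
  features <- features[ord, , drop = FALSE]
  out <- lapply(split(features, features$participant_id), function(df) {
    n <- nrow(df)
    if (n < t) return(NULL)
    if (t == 1) {
      res <- df[, feature_cols, drop = FALSE]
      anchors <- df$night_date
    } else {
      res <- as.data.frame(lapply(df[feature_cols], function(x) {
        w <- stats::embed(x, t) # row i = window ending at night i + t - 1
        mx <- do.call(pmax, as.data.frame(w))
        mn <- do.call(pmin, as.data.frame(w))
        (rowSums(w) - mx - mn) / (t - 2)
      }))
      anchors <- df$night_date[t:n]
    }
    cbind(data.frame(participant_id = df$participant_id[1],
                     anchor_night_date = anchors, t = t,
                     stringsAsFactors = FALSE),
          res)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- cbind(data.frame(participant_id = character(),
                            anchor_night_date = as.Date(character()),
                            t = integer()),
                 stats::setNames(as.data.frame(replicate(length(feature_cols),
                                                         numeric(0),
                                                         simplify = FALSE)),
                                 feature_cols))
  }
  rownames(res) <- NULL
  res
}

#' Names of the ten nightly features
#' @return character vector.
#' @export
nightly_feature_names <- function() {
  c("sdnn", "tp", "ulf", "vlf", "lf", "hf", "lf_hf", "hr_mode", "rr_mode", "rrf")
}
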