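# End-to-end study orchestration:
# simulate -> extract -> QC -> aggregate -> screen -> classify -> report.

#' Run the full nocturnal-monitoring classification study
#'
#' Generates (or extracts features from) a cohort, applies the night-level
#' QC exclusions, builds person-time samples of trimmed-mean features at
#' every configured timescale, screens features by rank test, fits
#' logistic-regression classifiers, and evaluates them on ROC curves. The
#' evaluated models mirror the usual reporting structure: the combined
#' model over all timescales at once, per-timescale all-feature models,
#' per-timescale category models (HRV / HR / respiration), and
#' single-feature models at the reference timescale with Youden-index
#' cutoffs in feature units.
#'
#' Model-based evaluations dichotomize the fitted probability at 0.5;
#' single-feature evaluations use the Youden cutoff. The combined model
#' and the between-timescale DeLong comparisons are computed on the subset
#' of anchor nights for which all timescale windows exist (so the
#' comparisons are paired). Everything is deterministic under the config
#' seed.
#'
#' @param config a [sim_config()].
#' @param level `"features"` (fast, default) or `"signal"` (full per-night
#'   signal synthesis and spectral feature extraction; use small cohorts).
#' @param screen_alpha screening level for [screen_features()].
#' @param reference_t timescale (days) used for single-feature evaluation
#'   and cutoffs; default 7.
#' @param cutoff_features features reported in the cutoff table.
#' @param out_dir optional directory; when given, all intermediate tables
#'   are written as CSV (`roster.csv`, `nights_index.csv`,
#'   `nightly_features.csv`, `qc_decisions.csv`, `samples_t<t>.csv`,
#'   `evaluation_t<t>.csv`, `evaluation_combined.csv`, `cutoffs.csv`).
#' @return object of class `study_report`; see Details.
#' @examples
#' \donttest{
#' rep <- run_study(sim_config(n_cases = 8, n_controls = 8,
#'                             nights_per_person = 20, seed = 3,
#'                             timescales = c(1, 7)))
#' rep$evaluations
#' }
#' @export
run_study <- function(config, level = c("features", "signal"),
                      screen_alpha = 0.05, reference_t = 7,
                      cutoff_features = c("hf", "rr_mode", "rrf"),
                      out_dir = NULL) {
  level <- match.arg(level)
  stage <- "simulate"
  withCallingHandlers({
    cohort <- generate_cohort(config, level = level)
    stage <- "extract"
    if (level == "signal") cohort <- extract_features(cohort)
    features <- cohort$features

    stage <- "qc"
    qc <- apply_night_exclusions(cohort$nights, features, cohort$roster,
                                 cohort$windows)
    kept <- filter_kept_nights(features, qc)
    kept$group <- cohort$roster$group[match(kept$participant_id,
                                            cohort$roster$participant_id)]
    drop_na <- !stats::complete.cases(kept[nightly_feature_names()])
    kept <- kept[!drop_na, , drop = FALSE]

    qc_summary <- list(
      nights_recorded = nrow(cohort$nights),
      nights_kept = sum(qc$kept),
      excluded_by_reason = colSums(
        sapply(c("motion", "sleep_short", "sleep_long", "data_loss",
                 "zero_vital", "exacerbation"),
               function(r) grepl(r, qc$reasons))
      )
    )

    stage <- "aggregate"
    ts <- config$timescales
    samples <- lapply(ts, function(t) {
      s <- build_samples(kept, t)
      s$group <- cohort$roster$group[match(s$participant_id,
                                           cohort$roster$participant_id)]
      s
    })
    names(samples) <- paste0("t", ts)
    qc_summary$samples_per_t <- stats::setNames(vapply(samples, nrow, integer(1)),
                                                paste0("t", ts))

    stage <- "screen"
    screening <- lapply(samples, screen_features, alpha = screen_alpha)

    stage <- "classify"
    eval_row <- function(model, t, rr) {
      data.frame(model = model, t = t, n_samples = rr$n_case + rr$n_control,
                 accuracy = rr$accuracy, sensitivity = rr$sensitivity,
                 specificity = rr$specificity, youden = rr$youden_index,
                 auc = rr$auc, ci_low = rr$ci[1], ci_high = rr$ci[2],
                 p_value = rr$p_value, cutoff = rr$cutoff,
                 stringsAsFactors = FALSE)
    }
    fit_and_eval <- function(df, feats) {
      fit <- fit_logistic(df, feats, on_separation = "warn")
      roc_evaluate(fit$fitted, df$group, decision_rule = "probability")
    }
    categories <- list(hrv = c("sdnn", "tp", "ulf", "vlf", "lf", "hf", "lf_hf"),
                       hr = "hr_mode",
                       respiration = c("rr_mode", "rrf"))
    evaluations <- list()
    roc_objects <- list()
    for (k in seq_along(ts)) {
      t <- ts[k]
      df <- samples[[k]]
      if (!nrow(df)) next
      retained <- screening[[k]]$retained
      if (length(retained)) {
        rr <- fit_and_eval(df, retained)
        roc_objects[[paste0("all_t", t)]] <- rr
        evaluations[[length(evaluations) + 1]] <- eval_row("all", t, rr)
      }
      for (cat in names(categories)) {
        feats <- intersect(categories[[cat]], retained)
        if (!length(feats)) next
        rr <- fit_and_eval(df, feats)
        roc_objects[[paste0(cat, "_t", t)]] <- rr
        evaluations[[length(evaluations) + 1]] <- eval_row(cat, t, rr)
      }
    }

    # combined model over all timescales on the anchors common to all t
    joined <- NULL
    joined_feats <- character(0)
    for (k in seq_along(ts)) {
      t <- ts[k]
      retained <- screening[[k]]$retained
      cols <- c("participant_id", "anchor_night_date", "group", retained)
      dfk <- samples[[k]][, cols, drop = FALSE]
      names(dfk)[-(1:3)] <- paste0(retained, "_t", t)
      joined_feats <- c(joined_feats, paste0(retained, "_t", t))
      joined <- if (is.null(joined)) dfk else
        merge(joined, dfk[, -3, drop = FALSE],
              by = c("participant_id", "anchor_night_date"))
    }
    comparisons <- NULL
    if (!is.null(joined) && nrow(joined) > 10 &&
        length(unique(joined$group)) == 2 && length(joined_feats)) {
      rr <- fit_and_eval(joined, joined_feats)
      roc_objects[["all_timescales"]] <- rr
      evaluations[[length(evaluations) + 1]] <-
        eval_row("all_timescales", NA_integer_, rr)
      # paired DeLong comparisons of adjacent timescales (all-feature models
      # refit on the common anchors)
      probs_t <- lapply(seq_along(ts), function(k) {
        f <- paste0(screening[[k]]$retained, "_t", ts[k])
        if (!length(f)) return(NULL)
        fit_logistic(joined, f, on_separation = "warn")$fitted
      })
      rows <- list()
      for (k in seq_len(length(ts) - 1)) {
        if (is.null(probs_t[[k]]) || is.null(probs_t[[k + 1]])) next
        cmp <- compare_auc(probs_t[[k + 1]], probs_t[[k]], joined$group)
        rows[[length(rows) + 1]] <- data.frame(
          model_a = paste0("all_t", ts[k + 1]), model_b = paste0("all_t", ts[k]),
          auc_a = cmp$auc_a, auc_b = cmp$auc_b, delta_auc = cmp$delta_auc,
          statistic = cmp$statistic, p_value = cmp$p_value,
          stringsAsFactors = FALSE
        )
      }
      if (length(rows)) comparisons <- do.call(rbind, rows)
    }
    evaluations <- do.call(rbind, evaluations)

    # single-feature evaluation and cutoffs at the reference timescale
    single <- NULL
    cutoffs <- NULL
    kref <- match(reference_t, ts)
    if (!is.na(kref) && nrow(samples[[kref]])) {
      dfr <- samples[[kref]]
      feats <- screening[[kref]]$retained
      rows <- lapply(feats, function(f) {
        rr <- roc_evaluate(dfr[[f]], dfr$group, decision_rule = "youden")
        data.frame(feature = f, t = reference_t, cutoff = rr$youden_cutoff,
                   accuracy = rr$accuracy, sensitivity = rr$sensitivity,
                   specificity = rr$specificity, youden = rr$youden_index,
                   auc = rr$auc, ci_low = rr$ci[1], ci_high = rr$ci[2],
                   p_value = rr$p_value, stringsAsFactors = FALSE)
      })
      single <- do.call(rbind, rows)
      cutoffs <- single[single$feature %in% cutoff_features,
                        c("feature", "cutoff", "sensitivity", "specificity",
                          "youden")]
    }

    stage <- "report"
    report <- structure(
      list(config = config, qc = qc, qc_summary = qc_summary,
           samples = samples, screening = screening,
           evaluations = evaluations, comparisons = comparisons,
           single_feature = single, cutoffs = cutoffs,
           roc = roc_objects,
           provenance = list(seed = config$seed,
                             config_hash = object_hash(config),
                             package_version = as.character(utils::packageVersion("nightsigns")),
                             r_version = R.version.string)),
      class = "study_report"
    )

    if (!is.null(out_dir)) {
      write_cohort(cohort, out_dir)
      utils::write.csv(qc, file.path(out_dir, "qc_decisions.csv"),
                       row.names = FALSE)
      for (k in seq_along(ts)) {
        utils::write.csv(samples[[k]],
                         file.path(out_dir, sprintf("samples_t%d.csv", ts[k])),
                         row.names = FALSE)
        utils::write.csv(evaluations[evaluations$t %in% ts[k], ],
                         file.path(out_dir, sprintf("evaluation_t%d.csv", ts[k])),
                         row.names = FALSE)
      }
      utils::write.csv(evaluations, file.path(out_dir, "evaluation_combined.csv"),
                       row.names = FALSE)
      if (!is.null(cutoffs)) {
        utils::write.csv(cutoffs, file.path(out_dir, "cutoffs.csv"),
                         row.names = FALSE)
      }
    }
    report
  }, error = function(e) {
    stop(sprintf("study stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat("Nocturnal vital-sign classification study\n")
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  cat(sprintf("  nights recorded %d, kept after QC %d\n",
              x$qc_summary$nights_recorded, x$qc_summary$nights_kept))
  cat("  person-time samples:",
      paste(sprintf("%s=%d", names(x$qc_summary$samples_per_t),
                    x$qc_summary$samples_per_t), collapse = ", "), "\n")
  excl <- x$screening[[1]]$excluded
  cat("  screened out at the nightly level:",
      if (length(excl)) paste(excl, collapse = ", ") else "none", "\n\n")
  print(x$evaluations, digits = 3, row.names = FALSE)
  if (!is.null(x$cutoffs)) {
    cat("\nSingle-feature Youden cutoffs (t =",
        x$single_feature$t[1], "days):\n")
    print(x$cutoffs, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
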