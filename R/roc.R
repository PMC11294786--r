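# ROC evaluation: curve, trapezoid AUC, DeLong interval, Youden cutoff.

#' Evaluate a score against case/control labels on the ROC curve
#'
#' Builds the ROC curve over all distinct score values (classification rule
#' "score at or above the threshold is a case"), computes the trapezoid
#' AUC — equal to the tie-corrected Mann-Whitney `U / (n1*n2)` — with a 95%
#' DeLong confidence interval and a DeLong-based two-sided p-value against
#' AUC = 0.5, and locates the Youden cutoff: the threshold maximizing
#' `sensitivity + specificity - 1`, ties resolved towards the lower
#' threshold.
#'
#' Accuracy, sensitivity and specificity are reported at the stated
#' decision rule: `"probability"` dichotomizes the score at `cutoff`
#' (default 0.5, the convention for fitted class probabilities), while
#' `"youden"` uses the Youden cutoff (the convention for single raw
#' features, whose cutoff is then in feature units). At the Youden rule
#' the reported Youden index equals `sensitivity + specificity - 1`
#' exactly.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels vector with both classes present; `positive` marks cases.
#' @param decision_rule `"probability"` or `"youden"`.
#' @param cutoff probability cutoff for the `"probability"` rule.
#' @param positive label value of the case class.
#' @return object of class `roc_result`: `curve` (threshold, fpr, tpr),
#'   `auc`, `ci` (95% DeLong), `p_value`, `youden_index`, `youden_cutoff`,
#'   `decision_rule`, `cutoff`, `accuracy`, `sensitivity`, `specificity`,
#'   `n_case`, `n_control`.
#' @export
roc_evaluate <- function(scores, labels, decision_rule = c("probability", "youden"),
                         cutoff = 0.5, positive = "case") {
  decision_rule <- match.arg(decision_rule)
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes must be present in 'labels'")
  if (length(scores) != length(y)) stop("'scores' and 'labels' lengths differ")

  th <- sort(unique(scores))
  tpr <- vapply(th, function(k) mean(scores[y] >= k), numeric(1))
  fpr <- vapply(th, function(k) mean(scores[!y] >= k), numeric(1))
  curve <- data.frame(threshold = c(th, Inf), fpr = c(fpr, 0), tpr = c(tpr, 0))
  curve <- curve[order(-curve$threshold), ]

  o <- order(curve$fpr, curve$tpr)
  fp <- curve$fpr[o]
  tp <- curve$tpr[o]
  auc <- sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)) / 2)

  j <- tpr - fpr
  jmax <- max(j)
  youden_cutoff <- min(th[j >= jmax - 1e-12])

  proc <- pROC::roc(response = factor(y, levels = c(FALSE, TRUE)),
                    predictor = scores, levels = c(FALSE, TRUE),
                    direction = "<", quiet = TRUE)
  # pROC warns that a degenerate (AUC = 1) curve has zero DeLong variance;
  # that case is handled explicitly below
  v <- suppressWarnings(pROC::var(proc, method = "delong"))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(proc, method = "delong"))[c(1, 3)])
  p_value <- if (v <= 0) {
    if (abs(auc - 0.5) < 1e-12) 1 else 0
  } else {
    2 * stats::pnorm(-abs((auc - 0.5) / sqrt(v)))
  }

  used_cutoff <- if (decision_rule == "probability") cutoff else youden_cutoff
  pred_case <- scores >= used_cutoff
  sens <- mean(pred_case[y])
  spec <- mean(!pred_case[!y])

  structure(
    list(curve = curve, auc = auc, ci = ci, auc_var = v, p_value = p_value,
         youden_index = jmax, youden_cutoff = youden_cutoff,
         decision_rule = decision_rule, cutoff = used_cutoff,
         accuracy = mean(pred_case == y), sensitivity = sens,
         specificity = spec, n_case = sum(y), n_control = sum(!y)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), p %s\n", x$auc,
              x$ci[1], x$ci[2], format.pval(x$p_value, digits = 3)))
  cat(sprintf("Youden index %.3f at cutoff %.4g (%s rule at %.4g)\n",
              x$youden_index, x$youden_cutoff, x$decision_rule, x$cutoff))
  cat(sprintf("accuracy %.3f, sensitivity %.3f, specificity %.3f (%d cases / %d controls)\n",
              x$accuracy, x$sensitivity, x$specificity, x$n_case, x$n_control))
  invisible(x)
}

#' DeLong paired comparison of two AUCs
#'
#' Tests the AUC difference of two scores computed on the *same* samples
#' (paired design) with the DeLong nonparametric variance of the
#' difference.
#'
#' @param scores_a,scores_b paired score vectors, same samples and order.
#' @param labels class labels; `positive` marks cases.
#' @param positive label value of the case class.
#' @return list with `statistic` (z), `p_value`, `auc_a`, `auc_b`,
#'   `delta_auc`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, positive = "case") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("'scores_a', 'scores_b' and 'labels' must have the same length")
  }
  y <- factor(labels == positive, levels = c(FALSE, TRUE))
  ra <- pROC::roc(response = y, predictor = scores_a,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = y, predictor = scores_b,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(statistic = 0, p_value = 1,
                auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)), delta_auc = 0))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(statistic = as.numeric(tst$statistic),
       p_value = tst$p.value,
       auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)),
       delta_auc = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)))
}
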