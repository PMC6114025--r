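#' Confusion-matrix statistics
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' misclassification rate = 100 * (FP + FN) / total. Undefined rates
#' (denominator zero) are flagged rather than computed. Values are stored at
#' full precision; rounding is a presentation concern.
#'
#' @param tp,fp,fn,tn non-negative counts, not all zero.
#' @return List: `tp`, `fp`, `fn`, `tn`, `n_total`, `sensitivity`,
#'   `specificity`, `misclassification_rate` (percent), and logical
#'   `sensitivity_defined`, `specificity_defined`.
#' @examples
#' confusion_stats(7, 56, 1, 191)  # sensitivity 0.875, specificity ~0.773
#' @export
confusion_stats <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn
  if (n == 0) stop("counts are all zero", call. = FALSE)
  sens_def <- (tp + fn) > 0
  spec_def <- (tn + fp) > 0
  list(
    tp = tp, fp = fp, fn = fn, tn = tn, n_total = n,
    sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
    specificity = if (spec_def) tn / (tn + fp) else NA_real_,
    misclassification_rate = 100 * (fp + fn) / n,
    sensitivity_defined = sens_def,
    specificity_defined = spec_def
  )
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique scores (ties grouped), yielding an ROC
#' polygon from (0,0) to (1,1); the AUC is the trapezoidal area, which equals
#' the rank-statistic AUC with ties counted one half.
#'
#' @param scores numeric classifier scores, higher = more case-like.
#' @param labels `"case"`/`"control"` (or logical case indicator), aligned
#'   with `scores`; both classes must be present.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == "case"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(pos & scores >= s) / n1, numeric(1))
  fpr <- vapply(thr, function(s) sum(!pos & scores >= s) / n0, numeric(1))
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                       threshold = c(Inf, thr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Evaluation report for scored subjects
#'
#' Builds the full confusion/ROC report: class calls at `threshold`, counts,
#' sensitivity/specificity/misclassification, and (when `scores` are
#' probabilities rather than hard class calls) the ROC polygon and AUC.
#'
#' @param scores numeric scores or probabilities; higher = more case-like.
#' @param labels `"case"`/`"control"` truth, aligned with `scores`.
#' @param threshold probability cutoff for calling a case.
#' @param with_auc compute the ROC/AUC component (disable for classifiers
#'   that only emit class labels, e.g. majority-vote forests).
#' @return An `evaluation_report` list: confusion fields as in
#'   [confusion_stats()], plus `auc` and `roc_points` (or `NA`/`NULL`).
#' @export
evaluation_report <- function(scores, labels, threshold = 0.5,
                              with_auc = TRUE) {
  call_case <- scores >= threshold
  truth_case <- labels == "case"
  rep_ <- confusion_stats(
    tp = sum(call_case & truth_case),
    fp = sum(call_case & !truth_case),
    fn = sum(!call_case & truth_case),
    tn = sum(!call_case & !truth_case)
  )
  if (with_auc) {
    roc <- roc_auc(scores, labels)
    rep_$auc <- roc$auc
    rep_$roc_points <- roc$points
  } else {
    rep_$auc <- NA_real_
    rep_$roc_points <- NULL
  }
  rep_$threshold <- threshold
  class(rep_) <- "evaluation_report"
  rep_
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d subjects (threshold %.2f):\n",
              x$n_total, x$threshold))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  misclassification %.1f%%\n",
              x$sensitivity, x$specificity, x$misclassification_rate))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}

#' Validate a fitted model on an external cohort
#'
#' Applies a fitted classifier unchanged to subjects that were not used in
#' training (enforced by subject-id disjointness) and reports confusion and
#' ROC statistics. Scoring is label-blind: the truth labels are only used
#' after all scores are computed. Majority-vote forest output yields class
#' labels only, so no AUC is reported in that mode.
#'
#' @param model a fitted `oculobox_model`.
#' @param metric_table metric table for the validation subjects.
#' @param cohort labeled validation cohort (needs `subject_id`,
#'   `case_label` or `group`, and `ct_status`).
#' @param exclude_ct_positive drop CT-positive cases before evaluating.
#' @param threshold class-call probability cutoff.
#' @param forest_mode `"vote"` (class labels, no AUC) or `"prob"`
#'   (out-of-vote probabilities, AUC reported; extension beyond the vote
#'   convention).
#' @return An `evaluation_report`.
#' @export
validate_external <- function(model, metric_table, cohort,
                              exclude_ct_positive = FALSE,
                              threshold = 0.5,
                              forest_mode = c("vote", "prob")) {
  forest_mode <- match.arg(forest_mode)
  overlap <- intersect(model$training_ids, cohort$subject_id)
  if (length(overlap)) {
    stop("validation subjects overlap the training set: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  if (!"case_label" %in% names(cohort)) {
    cohort$case_label <- ifelse(cohort$group == "case", "case", "control")
  }
  if (exclude_ct_positive) {
    cohort <- cohort[!(cohort$case_label == "case" &
                         !is.na(cohort$ct_status) &
                         cohort$ct_status == "positive"), ]
  }
  tab <- metric_table[match(cohort$subject_id, metric_table$subject_id), ]
  scores <- predict_oculobox(model, tab, type = if (
    model$method == "random_forest" && forest_mode == "vote") "class"
    else "prob")
  with_auc <- !(model$method == "random_forest" && forest_mode == "vote")
  evaluation_report(scores, cohort$case_label, threshold = threshold,
                    with_auc = with_auc)
}
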