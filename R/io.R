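# File formats: recordings and cohorts travel as CSV, metric/screening/report
# tables as TSV, models and manifests as JSON. Missing coordinates are empty
# fields in the recording CSV.

#' Write a recording to CSV
#'
#' Columns exactly `t,left_x,left_y,right_x,right_y,valid_left,valid_right`;
#' missing coordinates are written as empty fields, validity as 0/1.
#'
#' @param recording a `raw_recording`.
#' @param path output file.
#' @export
write_recording <- function(recording, path) {
  df <- data.frame(
    t = recording$timestamps,
    left_x = recording$left_x, left_y = recording$left_y,
    right_x = recording$right_x, right_y = recording$right_y,
    valid_left = as.integer(recording$valid_left),
    valid_right = as.integer(recording$valid_right)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path file written by [write_recording()] (or any file with the
#'   same column contract).
#' @param protocol the [stimulus_protocol()] the recording follows.
#' @param subject_id identifier to attach; default the file name stem.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path, protocol = stimulus_protocol(),
                           subject_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "left_x", "left_y", "right_x", "right_y",
            "valid_left", "valid_right")
  if (!all(need %in% names(df))) {
    stop("recording file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  new_raw_recording(subject_id, df$t, df$left_x, df$left_y,
                    df$right_x, df$right_y,
                    as.logical(df$valid_left), as.logical(df$valid_right),
                    protocol)
}

#' Write / read a cohort table
#'
#' CSV with columns `subject_id,age,sex,group,ct_status,sss,sac` (plus
#' `case_label` when present).
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a metric table (TSV, one row per subject)
#' @param metric_table data frame with `subject_id` and metric columns.
#' @param path file path.
#' @export
write_metric_table <- function(metric_table, path) {
  utils::write.table(metric_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export a box trajectory as CSV (`phase_bin,eye,x,y,n`)
#' @param trajectory a `box_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Serialize / load a fitted model as JSON
#'
#' Stores method, selected metrics, coefficients, seed and diagnostics.
#' Forest models store their configuration and OOB error but not the tree
#' structure; reload refits from data when needed.
#'
#' @param model an `oculobox_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    method = model$method,
    selected = model$selected,
    coefficients = as.list(model$coefficients),
    training_ids = model$training_ids,
    seed = model$seed,
    apparent_auc = model$apparent_auc,
    apparent_misclassification = model$apparent_misclassification,
    oob_error = model$oob_error
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_oculobox_model(
    obj$method, obj$selected %||% character(0),
    coefficients = unlist(obj$coefficients),
    training_ids = obj$training_ids, seed = obj$seed,
    extra = list(apparent_auc = obj$apparent_auc,
                 apparent_misclassification = obj$apparent_misclassification,
                 oob_error = obj$oob_error))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an evaluation report as TSV, and its ROC points as CSV
#' @param report an `evaluation_report`.
#' @param path TSV output path.
#' @export
write_report <- function(report, path) {
  df <- data.frame(
    misclassification_rate = report$misclassification_rate,
    tp = report$tp, fp = report$fp, fn = report$fn, tn = report$tn,
    sensitivity = report$sensitivity, specificity = report$specificity,
    auc = report$auc
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_report
#' @param roc_path CSV output path for the ROC points.
#' @export
write_roc_points <- function(report, roc_path) {
  if (is.null(report$roc_points)) {
    stop("report carries no ROC points", call. = FALSE)
  }
  utils::write.csv(report$roc_points, roc_path, row.names = FALSE,
                   quote = FALSE)
  invisible(roc_path)
}
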