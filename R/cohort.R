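#' Concussion case labeling
#'
#' A trauma subject is labeled a concussion "true positive" when the head CT
#' is negative for structural injury, the SCAT3 symptom severity score is
#' strictly greater than 40, and the SCAT3 cognitive subscore is at most 24.
#' Missing CT status or scores make the subject not labelable (`NA`), which
#' is distinct from `FALSE`.
#'
#' @param ct_status `"positive"`, `"negative"` or `"none"`/`NA`; vectorized.
#' @param sss SCAT3 symptom severity score (0-132).
#' @param sac SCAT3 standardized assessment of concussion score (0-30).
#' @return Logical vector: `TRUE` (case), `FALSE`, or `NA` (not labelable).
#' @examples
#' label_concussion("negative", 41, 24)  # TRUE
#' label_concussion("negative", 40, 24)  # FALSE
#' label_concussion("positive", 90, 10)  # FALSE (structural injury)
#' @export
label_concussion <- function(ct_status, sss, sac) {
  out <- rep(NA, length(ct_status))
  known <- !is.na(ct_status) & ct_status != "none" & !is.na(sss) & !is.na(sac)
  out[known] <- ct_status[known] == "negative" &
    sss[known] > 40 & sac[known] <= 24
  out
}

#' Attach a case/control label column to a cohort table
#'
#' Controls keep the label `"control"`; trauma subjects are labeled `"case"`
#' or `"control"` by [label_concussion()], or `"unlabeled"` when the required
#' fields are missing.
#'
#' @param cohort cohort data frame with `group`, `ct_status`, `sss`, `sac`.
#' @return The cohort with an added `case_label` column.
#' @export
label_cohort <- function(cohort) {
  lab <- rep("control", nrow(cohort))
  trauma <- cohort$group != "control"
  lc <- label_concussion(cohort$ct_status[trauma], cohort$sss[trauma],
                         cohort$sac[trauma])
  lab[trauma] <- ifelse(is.na(lc), "unlabeled",
                        ifelse(lc, "case", "control"))
  cohort$case_label <- lab
  cohort
}

#' Build an age/sex-balanced 1:1 analysis sample
#'
#' Nearest-neighbor matching on age without replacement: optionally restrict
#' both groups to one sex, then for each case (visited in random order under
#' `seed`) select the unused control closest in age, ties broken at random.
#' The achieved age balance is reported as a Wilcoxon rank-sum p-value.
#'
#' @param cohort cohort data frame with `subject_id`, `age`, `sex`, `group`.
#' @param restrict_sex `NULL`, `"male"` or `"female"`.
#' @param seed integer seed for visit order and tie-breaks.
#' @return A list with `sample` (the balanced cohort subset), `age_p`
#'   (rank-sum p-value for age, cases vs matched controls), and
#'   `matched_pairs` (data frame of case/control ids).
#' @export
balance_sample <- function(cohort, restrict_sex = NULL, seed = 1L) {
  pool <- cohort
  if (!is.null(restrict_sex)) pool <- pool[pool$sex == restrict_sex, ]
  cases <- pool[pool$group == "case", ]
  controls <- pool[pool$group == "control", ]
  if (nrow(cases) == 0) {
    stop("infeasible matching: no cases in the pool",
         if (!is.null(restrict_sex)) paste0(" for sex ", restrict_sex),
         call. = FALSE)
  }
  if (nrow(controls) < nrow(cases)) {
    stop("infeasible matching: ", nrow(cases), " cases but only ",
         nrow(controls), " controls",
         if (!is.null(restrict_sex)) paste0(" of sex ", restrict_sex),
         call. = FALSE)
  }
  set.seed(seed)
  order_cases <- sample.int(nrow(cases))
  used <- rep(FALSE, nrow(controls))
  pairs <- data.frame(case_id = character(0), control_id = character(0))
  for (i in order_cases) {
    d <- abs(controls$age - cases$age[i])
    d[used] <- Inf
    best <- which(d == min(d))
    pick <- if (length(best) > 1L) sample(best, 1L) else best
    used[pick] <- TRUE
    pairs <- rbind(pairs, data.frame(case_id = cases$subject_id[i],
                                     control_id = controls$subject_id[pick]))
  }
  keep <- cohort$subject_id %in% c(pairs$case_id, pairs$control_id)
  sample_out <- cohort[keep, ]
  age_p <- wilcoxon_rank_sum(cases$age,
                             controls$age[used])$p.value
  list(sample = sample_out, age_p = age_p, matched_pairs = pairs)
}

#' Restrict cases by CT status
#'
#' With `keep = "ct_negative_only"`, drops CT-positive cases so the analysis
#' focuses on concussion rather than structural injury; controls are never
#' touched. Warns if no cases remain.
#'
#' @param cohort cohort data frame with `group` and `ct_status`.
#' @param keep `"all"` or `"ct_negative_only"`.
#' @return The filtered cohort.
#' @export
filter_ct <- function(cohort, keep = c("all", "ct_negative_only")) {
  keep <- match.arg(keep)
  if (keep == "all") return(cohort)
  drop <- cohort$group == "case" & cohort$ct_status == "positive"
  out <- cohort[!drop, ]
  if (!any(out$group == "case")) {
    warning("no CT-negative cases remain after filtering", call. = FALSE)
  }
  out
}
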