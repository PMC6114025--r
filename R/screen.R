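#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks handle ties. For `min(n_a, n_b) <= exact_limit` the null
#' distribution of the rank sum is obtained by complete enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments of the observed (mid)ranks,
#' which stays exact under ties; larger samples use the normal approximation
#' with tie correction and continuity correction. If every pooled value is
#' identical the test is vacuous and p = 1.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param exact_limit switch to enumeration when `min(n) <=` this.
#' @return List with `statistic` (rank sum of `a`), `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each sample needs >= 2 values", call. = FALSE)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = sum(rank(pooled)[seq_len(n1)]), p.value = 1,
                method = "degenerate"))
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  if (min(n1, n2) <= exact_limit && choose(n1 + n2, n1) <= 5e5) {
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    eps <- 1e-9
    p_lo <- mean(sums <= w + eps)
    p_hi <- mean(sums >= w - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = w, p.value = p, method = "exact enumeration"))
  }
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p.value = p, method = "normal approximation")
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests; must be >= 1.
#' @return `alpha / m` (0.05 / 89 = 0.000562 for the default metric family).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 89L) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Area under the ROC curve for a single metric
#'
#' The probability that a randomly chosen case value exceeds a randomly
#' chosen control value, with ties counted one half (the Mann-Whitney / rank
#' sum identity: `AUC = U / (n_case * n_control)`).
#'
#' @param case_values,control_values numeric vectors, both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
metric_auc <- function(case_values, control_values) {
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  n1 <- length(case_values); n0 <- length(control_values)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(case_values, control_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Age and sex association screen on the control sample
#'
#' For each metric, computes the sex association (rank-sum test, male vs
#' female) and age association (Spearman rank correlation with t
#' approximation) on the full control sample, and flags for exclusion every
#' metric with `p_sex <= p_sex_cut` or `p_age <= p_age_cut` (inclusive
#' thresholds). A single-sex sample skips the sex screen with a warning.
#'
#' @param metric_table metric data frame (control rows).
#' @param demographics data frame with `subject_id`, `age`, `sex` aligned by
#'   `subject_id`.
#' @param metrics metric column names to screen; defaults to all 89.
#' @param p_sex_cut,p_age_cut inclusive exclusion thresholds.
#' @return Data frame: `metric`, `p_sex`, `p_age`, `excluded_by_covariate`.
#' @export
covariate_screen <- function(metric_table, demographics,
                             metrics = intersect(metric_names(),
                                                 names(metric_table)),
                             p_sex_cut = 0.01, p_age_cut = 0.05) {
  dem <- demographics[match(metric_table$subject_id, demographics$subject_id), ]
  both_sexes <- length(unique(dem$sex)) > 1L
  if (!both_sexes) {
    warning("single-sex control sample: sex screen skipped", call. = FALSE)
  }
  rows <- lapply(metrics, function(m) {
    v <- metric_table[[m]]
    ok <- !is.na(v)
    p_sex <- NA_real_
    if (both_sexes && sum(ok & dem$sex == "male") >= 2 &&
        sum(ok & dem$sex == "female") >= 2) {
      p_sex <- wilcoxon_rank_sum(v[ok & dem$sex == "male"],
                                 v[ok & dem$sex == "female"])$p.value
    }
    p_age <- NA_real_
    if (sum(ok) >= 3 && stats::sd(v[ok]) > 0) {
      ct <- suppressWarnings(
        stats::cor.test(v[ok], dem$age[ok], method = "spearman",
                        exact = FALSE))
      p_age <- ct$p.value
    }
    data.frame(metric = m, p_sex = p_sex, p_age = p_age,
               excluded_by_covariate =
                 (!is.na(p_sex) && p_sex <= p_sex_cut) ||
                 (!is.na(p_age) && p_age <= p_age_cut),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Drop all-but-one of each block of highly correlated metrics
#'
#' Builds the graph whose edges join metric pairs with absolute Spearman
#' correlation above `r_cut` and keeps one representative per connected
#' component: the metric with the smallest group-contrast p-value, ties
#' broken lexicographically by name.
#'
#' @param metric_table data frame with the candidate metric columns.
#' @param candidates metric names to deduplicate.
#' @param p_group named vector of group-contrast p-values for the candidates.
#' @param r_cut absolute Spearman correlation threshold (exclusive).
#' @return Character vector of retained metric names.
#' @export
dedup_correlated <- function(metric_table, candidates, p_group,
                             r_cut = 0.9) {
  k <- length(candidates)
  if (k <= 1L) return(candidates)
  x <- as.matrix(metric_table[, candidates, drop = FALSE])
  r <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  # union-find over the |r| > r_cut graph
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (abs(r[i, j]) > r_cut) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  keep <- character(0)
  for (cp in unique(comp)) {
    members <- candidates[comp == cp]
    pv <- p_group[members]
    pv[is.na(pv)] <- Inf
    members <- members[order(pv, members)]
    keep <- c(keep, members[1L])
  }
  sort(keep)
}

#' Univariate biomarker screening table
#'
#' Runs the full screening stage: group contrast (case vs control rank-sum
#' tests with the Bonferroni family threshold `alpha / m`), covariate
#' exclusion on the full control sample, per-metric AUC, and correlation
#' deduplication among the candidates that survive both filters at the
#' nominal `p < alpha` level.
#'
#' @param metric_table metric table for the balanced analysis sample.
#' @param labels named or aligned character vector, `"case"`/`"control"`,
#'   one per row of `metric_table`.
#' @param control_table metric table for the full control sample (covariate
#'   screen); defaults to the control rows of `metric_table`.
#' @param control_demographics demographics for `control_table`.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param p_sex_cut,p_age_cut covariate exclusion thresholds.
#' @param r_cut deduplication correlation threshold.
#' @return A `screening_table` data frame with one row per metric: `metric`,
#'   `p_group`, `p_sex`, `p_age`, `auc`, `pass_bonferroni`,
#'   `excluded_by_covariate`, `dropped_as_duplicate`, `candidate`, plus
#'   attributes `threshold` and `retained` (final candidate set).
#' @export
screen_metrics <- function(metric_table, labels,
                           control_table = NULL,
                           control_demographics = NULL,
                           alpha = 0.05,
                           p_sex_cut = 0.01, p_age_cut = 0.05,
                           r_cut = 0.9) {
  metrics <- intersect(metric_names(), names(metric_table))
  m <- length(metrics)
  thr <- bonferroni_threshold(alpha, m)
  is_case <- labels == "case"

  p_group <- auc <- stats::setNames(rep(NA_real_, m), metrics)
  for (mm in metrics) {
    v <- metric_table[[mm]]
    ca <- v[is_case & !is.na(v)]
    co <- v[!is_case & !is.na(v)]
    if (length(ca) >= 2 && length(co) >= 2) {
      p_group[mm] <- wilcoxon_rank_sum(ca, co)$p.value
      auc[mm] <- metric_auc(ca, co)
    }
  }

  if (is.null(control_table)) control_table <- metric_table[!is_case, ]
  if (is.null(control_demographics)) {
    cov <- data.frame(metric = metrics, p_sex = NA_real_, p_age = NA_real_,
                      excluded_by_covariate = FALSE, stringsAsFactors = FALSE)
  } else {
    cov <- covariate_screen(control_table, control_demographics, metrics,
                            p_sex_cut, p_age_cut)
  }
  cov <- cov[match(metrics, cov$metric), ]

  out <- data.frame(
    metric = metrics,
    p_group = unname(p_group),
    p_sex = cov$p_sex,
    p_age = cov$p_age,
    auc = unname(auc),
    pass_bonferroni = !is.na(p_group) & p_group < thr,
    excluded_by_covariate = cov$excluded_by_covariate,
    stringsAsFactors = FALSE
  )
  candidates <- out$metric[!out$excluded_by_covariate &
                             !is.na(out$p_group) & out$p_group < alpha]
  retained <- if (length(candidates)) {
    dedup_correlated(metric_table, candidates, p_group[candidates], r_cut)
  } else character(0)
  out$candidate <- out$metric %in% candidates
  out$dropped_as_duplicate <- out$candidate & !(out$metric %in% retained)
  attr(out, "threshold") <- thr
  attr(out, "retained") <- retained
  class(out) <- c("screening_table", "data.frame")
  out
}
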