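new_oculobox_model <- function(method, selected, coefficients, training_ids,
                               seed = NA_integer_, extra = list()) {
  structure(
    c(list(method = method, selected = selected, coefficients = coefficients,
           training_ids = training_ids, seed = seed), extra),
    class = "oculobox_model"
  )
}

#' @export
print.oculobox_model <- function(x, ...) {
  cat(sprintf("oculobox %s model, %d predictor(s): %s\n", x$method,
              length(x$selected),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(intercept only)"))
  if (!is.null(x$apparent_auc) && !is.na(x$apparent_auc)) {
    cat(sprintf("  apparent AUC %.3f, apparent misclassification %.1f%%\n",
                x$apparent_auc, x$apparent_misclassification))
  }
  if (!is.null(x$oob_error)) {
    cat(sprintf("  OOB misclassification %.1f%%\n", x$oob_error))
  }
  invisible(x)
}

#' Predict case probabilities (or class calls) from a fitted model
#'
#' @param model an `oculobox_model`.
#' @param metric_table data frame containing the model's predictor columns.
#' @param type `"prob"` or `"class"` (class calls at probability 0.5).
#' @return Numeric vector, one score per row.
#' @export
predict_oculobox <- function(model, metric_table, type = c("prob", "class")) {
  type <- match.arg(type)
  if (model$method == "random_forest") {
    X <- as.matrix(metric_table[, model$selected, drop = FALSE])
    return(predict_forest(model$forest, X, type))
  }
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(metric_table))
  for (m in model$selected) {
    eta <- eta + model$coefficients[[m]] * metric_table[[m]]
  }
  p <- stats::plogis(eta)
  if (type == "class") as.numeric(p >= 0.5) else p
}

apparent_diagnostics <- function(model, metric_table, labels) {
  p <- predict_oculobox(model, metric_table, "prob")
  ok <- !is.na(p)
  model$apparent_auc <- tryCatch(
    metric_auc(p[ok & labels == "case"], p[ok & labels == "control"]),
    error = function(e) NA_real_)
  model$apparent_misclassification <-
    100 * mean((p[ok] >= 0.5) != (labels[ok] == "case"))
  model
}

prepare_design <- function(metric_table, labels, candidates,
                           missing = c("drop_rows", "drop_columns")) {
  missing <- match.arg(missing)
  df <- metric_table[, candidates, drop = FALSE]
  if (missing == "drop_columns") {
    keep <- !vapply(df, anyNA, logical(1))
    if (!all(keep)) df <- df[, keep, drop = FALSE]
    rows <- rep(TRUE, nrow(df))
  } else {
    rows <- stats::complete.cases(df)
    df <- df[rows, , drop = FALSE]
  }
  constant <- vapply(df, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("dropping constant predictor(s): ",
            paste(names(df)[constant], collapse = ", "), call. = FALSE)
    df <- df[, !constant, drop = FALSE]
  }
  list(x = df, rows = rows,
       y = as.numeric(labels[rows] == "case"),
       ids = metric_table$subject_id[rows])
}

# Weak-ridge logistic fit by penalized IRLS (intercept unpenalized); used as
# the fallback when a winning subset is completely separated.
ridge_logistic <- function(xm, y, lambda = 1e-3, maxit = 100L) {
  p <- ncol(xm)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(xm %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new_beta <- solve(crossprod(xm, xm * w) + pen, crossprod(xm, w * z))
    if (max(abs(new_beta - beta)) < 1e-10) break
    beta <- drop(new_beta)
  }
  stats::setNames(drop(beta), colnames(xm))
}

fit_logistic_aic <- function(x, y) {
  xm <- cbind(`(Intercept)` = 1, as.matrix(x))
  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial()))
  k <- ncol(xm)
  list(coef = stats::setNames(fit$coefficients, colnames(xm)),
       aic = fit$deviance + 2 * k,
       separated = !fit$converged || any(abs(fit$coefficients) > 15,
                                         na.rm = TRUE))
}

#' Best-subset logistic classifier
#'
#' Exhaustively searches all predictor subsets up to `max_subset_size` and
#' keeps the logistic model with the smallest AIC (the intercept-only model
#' is in the running, so pure-noise candidates collapse to no predictors).
#' Rows or columns with missing values are dropped according to `missing`,
#' mirroring the two ways a missing constituent can be handled. If the
#' winning subset shows complete separation, the coefficients are refit with
#' a weak ridge penalty and a warning.
#'
#' @param metric_table metric data frame for the training sample.
#' @param labels `"case"`/`"control"`, one per row.
#' @param candidates candidate metric names.
#' @param max_subset_size largest subset searched.
#' @param missing `"drop_rows"` (complete cases) or `"drop_columns"`.
#' @return An `oculobox_model` with apparent (training) diagnostics.
#' @export
fit_best_subset <- function(metric_table, labels, candidates,
                            max_subset_size = 5L,
                            missing = "drop_rows") {
  if (!length(candidates)) stop("no candidate metrics", call. = FALSE)
  d <- prepare_design(metric_table, labels, candidates, missing)
  vars <- names(d$x)
  best <- list(subset = character(0), fit = fit_logistic_aic(
    d$x[, character(0), drop = FALSE], d$y))
  for (k in seq_len(min(max_subset_size, length(vars)))) {
    combos <- utils::combn(vars, k, simplify = FALSE)
    for (cb in combos) {
      f <- fit_logistic_aic(d$x[, cb, drop = FALSE], d$y)
      if (f$aic < best$fit$aic) best <- list(subset = cb, fit = f)
    }
  }
  coefs <- best$fit$coef
  if (best$fit$separated) {
    warning("winning subset is separated; refitting with weak ridge penalty",
            call. = FALSE)
    xm <- cbind(`(Intercept)` = 1,
                as.matrix(d$x[, best$subset, drop = FALSE]))
    coefs <- ridge_logistic(xm, d$y)
  }
  model <- new_oculobox_model(
    "best_subset", best$subset, coefs,
    training_ids = d$ids,
    extra = list(aic = best$fit$aic, missing_policy = missing))
  apparent_diagnostics(model, metric_table[d$rows, , drop = FALSE],
                       labels[d$rows])
}

#' L1-penalized logistic classifier
#'
#' Fits the lasso path with internal standardization; the penalty is chosen
#' by internal cross-validation of the binomial deviance under `seed`
#' (`rule = "min"`, or the sparser `"1se"` rule). Supplying `lambda`
#' bypasses the cross-validation (``lambda = 0`` approximates the
#' unpenalized maximum-likelihood fit). Selected metrics are those with
#' nonzero coefficients.
#'
#' @inheritParams fit_best_subset
#' @param seed RNG seed for the internal fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @param lambda optional fixed penalty.
#' @param nfolds internal cross-validation folds.
#' @return An `oculobox_model`.
#' @export
fit_lasso <- function(metric_table, labels, candidates, seed = 1L,
                      rule = c("min", "1se"), lambda = NULL, nfolds = 10L,
                      missing = "drop_rows") {
  rule <- match.arg(rule)
  if (!length(candidates)) stop("no candidate metrics", call. = FALSE)
  d <- prepare_design(metric_table, labels, candidates, missing)
  xm <- as.matrix(d$x)
  if (ncol(xm) < 2L) {
    # glmnet needs >= 2 columns; with one candidate the lasso path is
    # equivalent to keeping or dropping it, so fit it unpenalized
    f <- fit_logistic_aic(d$x, d$y)
    model <- new_oculobox_model(
      "lasso", colnames(xm), f$coef, training_ids = d$ids, seed = seed,
      extra = list(lambda = 0, rule = rule, missing_policy = missing))
    return(apparent_diagnostics(model, metric_table[d$rows, , drop = FALSE],
                                labels[d$rows]))
  }
  # small-n logistic paths routinely fail to converge at the smallest
  # lambdas (near-separation); glmnet returns the converged prefix, which is
  # all the cross-validation uses, so those warnings are noise here
  quiet_glmnet <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("from glmnet C\\+\\+ code", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  if (is.null(lambda)) {
    set.seed(seed)
    cv <- quiet_glmnet(
      glmnet::cv.glmnet(xm, d$y, family = "binomial", nfolds = nfolds,
                        standardize = TRUE))
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    fitobj <- cv$glmnet.fit
  } else {
    fitobj <- quiet_glmnet(
      glmnet::glmnet(xm, d$y, family = "binomial", standardize = TRUE,
                     lambda = if (lambda == 0) c(0.1, 0) else lambda,
                     thresh = 1e-12))
  }
  cf <- stats::coef(fitobj, s = lambda, exact = FALSE)
  coefs <- stats::setNames(as.numeric(cf), rownames(cf))
  selected <- setdiff(names(coefs)[coefs != 0], "(Intercept)")
  model <- new_oculobox_model(
    "lasso", selected, coefs[c("(Intercept)", selected)],
    training_ids = d$ids, seed = seed,
    extra = list(lambda = lambda, rule = rule, missing_policy = missing))
  apparent_diagnostics(model, metric_table[d$rows, , drop = FALSE],
                       labels[d$rows])
}

#' Random-forest classifier with out-of-bag error
#'
#' Bagged CART ensemble (see [bagged_forest()]); the out-of-bag
#' misclassification rate (percent) estimates generalization error without a
#' separate validation split.
#'
#' @inheritParams fit_best_subset
#' @param n_trees ensemble size.
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param seed RNG seed; fixed seed gives identical forests and OOB error.
#' @return An `oculobox_model` with `oob_error` (percent).
#' @export
fit_random_forest <- function(metric_table, labels, candidates,
                              n_trees = 500L, mtry = NULL, seed = 1L,
                              missing = "drop_rows") {
  if (!length(candidates)) stop("no candidate metrics", call. = FALSE)
  d <- prepare_design(metric_table, labels, candidates, missing)
  forest <- bagged_forest(as.matrix(d$x), d$y, n_trees = n_trees,
                          mtry = mtry, seed = seed)
  new_oculobox_model(
    "random_forest", names(d$x), coefficients = NULL,
    training_ids = d$ids, seed = seed,
    extra = list(forest = forest, oob_error = forest$oob_error,
                 n_trees = n_trees, missing_policy = missing))
}

fit_by_method <- function(method, metric_table, labels, candidates, seed,
                          max_subset_size = 5L, n_trees = 500L,
                          missing = "drop_rows", fixed_subset = NULL) {
  if (!is.null(fixed_subset)) {
    # refit-only mode (used to demonstrate selection leakage): the subset is
    # taken as given and only coefficients are estimated on this data
    d <- prepare_design(metric_table, labels, fixed_subset, missing)
    f <- fit_logistic_aic(d$x, d$y)
    return(new_oculobox_model("best_subset", names(d$x), f$coef, d$ids))
  }
  switch(method,
    best_subset = fit_best_subset(metric_table, labels, candidates,
                                  max_subset_size, missing),
    lasso = fit_lasso(metric_table, labels, candidates, seed = seed,
                      missing = missing),
    random_forest = fit_random_forest(metric_table, labels, candidates,
                                      n_trees = n_trees, seed = seed,
                                      missing = missing),
    stop("unknown method: ", method)
  )
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, subjects are assigned to `n_folds` folds stratified by
#' class; the full model-selection procedure is re-run inside every training
#' fold (no selection leakage), held-out subjects are scored, and the pooled
#' out-of-fold scores give one AUC and one misclassification rate per
#' repeat. Means over repeats are reported.
#'
#' The `leak_selection` flag exists only to demonstrate the anti-pattern it
#' guards against: selection is then performed once on the full data and
#' only the coefficients are re-estimated per fold, which optimistically
#' biases the cross-validated AUC.
#'
#' @param metric_table metric data frame.
#' @param labels `"case"`/`"control"` per row; both classes need at least
#'   `n_folds` members.
#' @param method `"best_subset"`, `"lasso"` or `"random_forest"`.
#' @param candidates candidate metric names.
#' @param n_folds folds per repeat.
#' @param n_repeats repeats; the reference analysis uses 1000, scale down
#'   for constrained runtimes.
#' @param seed master seed; per-repeat and per-fold seeds derive from it.
#' @param threshold class-call probability cutoff.
#' @param max_subset_size,n_trees,missing passed to the fitters.
#' @param leak_selection see above; keep `FALSE` outside demonstrations.
#' @return A `cv_result` list: `mean_auc`, `mean_misclassification`
#'   (percent), per-repeat vectors `auc` and `misclassification`, `n_folds`,
#'   `n_repeats`, `seed`.
#' @export
repeated_cv <- function(metric_table, labels, method, candidates,
                        n_folds = 4L, n_repeats = 1000L, seed = 1L,
                        threshold = 0.5, max_subset_size = 5L,
                        n_trees = 500L, missing = "drop_rows",
                        leak_selection = FALSE) {
  is_case <- labels == "case"
  if (sum(is_case) < n_folds || sum(!is_case) < n_folds) {
    stop("each class needs at least n_folds members for stratification",
         call. = FALSE)
  }
  fixed_subset <- NULL
  if (leak_selection) {
    full <- fit_by_method(method, metric_table, labels, candidates, seed,
                          max_subset_size, n_trees, missing)
    fixed_subset <- full$selected
    if (!length(fixed_subset)) fixed_subset <- candidates[1]
  }
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  n <- nrow(metric_table)
  auc <- mis <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    fold <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(is_case == cls)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
    scores <- rep(NA_real_, n)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      model <- fit_by_method(method, metric_table[tr, , drop = FALSE],
                             labels[tr], candidates,
                             seed = repeat_seeds[r] %% 1000000L + f,
                             max_subset_size, n_trees, missing,
                             fixed_subset = fixed_subset)
      scores[!tr] <- predict_oculobox(
        model, metric_table[!tr, , drop = FALSE], "prob")
    }
    ok <- !is.na(scores)
    auc[r] <- metric_auc(scores[ok & is_case], scores[ok & !is_case])
    mis[r] <- 100 * mean((scores[ok] >= threshold) != is_case[ok])
  }
  structure(
    list(mean_auc = mean(auc), mean_misclassification = mean(mis),
         auc = auc, misclassification = mis,
         n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validation, %d repeat(s): mean AUC %.3f, mean misclassification %.1f%%\n",
    x$n_folds, x$n_repeats, x$mean_auc, x$mean_misclassification))
  invisible(x)
}
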